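test_that("sse_objective sums squared residuals across datasets", {
  ds1 <- ts_dataset(1:3, c(1, 2, 3))
  ds2 <- ts_dataset(1:2, c(5, 5))
  sim_perfect <- function(p, d) d$mean
  expect_equal(sse_objective(NULL, ds1, sim_perfect), 0)
  sim3 <- function(p, d) rep(3, nrow(d))
  expect_equal(sse_objective(NULL, ts_dataset(1, 1), sim3), 4)
  both <- sse_objective(NULL, list(ds1, ds2), sim3)
  expect_equal(both,
               sse_objective(NULL, ds1, sim3) + sse_objective(NULL, ds2, sim3))
  # failure maps to a large finite penalty
  expect_equal(sse_objective(NULL, ds1, function(p, d) stop("boom")), 1e12)
  # SEM weighting divides each residual by its variance
  dsw <- ts_dataset(1:2, c(10, 100), sem = c(1, 10))
  simw <- function(p, d) d$mean + c(1, 10)
  expect_equal(sse_objective(NULL, dsw, simw, weight_sem = TRUE), 2)
})

test_that("r_squared matches hand-computed values and rejects degenerate input", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(2, 4, 6)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(1), c(1)), "at least 2")
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("hooke_jeeves finds known minima and respects bounds", {
  fit <- hooke_jeeves(function(x) (x - 3)^2, 0, steps = 1, tol = 1e-8)
  expect_equal(fit$par, 3, tolerance = 1e-4)
  expect_lte(fit$value, (0 - 3)^2)

  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  fit2 <- hooke_jeeves(rosen, c(-1.2, 1), steps = 0.5, tol = 1e-10,
                       max_evals = 2e5)
  expect_equal(fit2$par, c(1, 1), tolerance = 1e-3)
  # agreement with an independent optimizer
  ref <- optim(c(-1.2, 1), rosen, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 1e4))
  expect_equal(fit2$value, ref$value, tolerance = 1e-4)

  # constrained optimum lands on the boundary
  fit3 <- hooke_jeeves(function(x) (x - 3)^2, 0.5, steps = 0.2,
                       lower = 0, upper = 1, tol = 1e-8)
  expect_equal(fit3$par, 1, tolerance = 1e-6)
  expect_error(hooke_jeeves(function(x) NaN, 0), "finite")
})

test_that("the returned optimum never exceeds any accepted iterate", {
  evals <- numeric(0)
  obj <- function(x) {
    v <- sum((x - c(2, -1))^2) + 0.3 * sin(5 * x[1])
    evals <<- c(evals, v)
    v
  }
  fit <- hooke_jeeves(obj, c(0, 0), steps = 0.7, tol = 1e-7)
  expect_equal(fit$value, min(evals))
  expect_lte(fit$value, evals[1])
})

test_that("multi-start ensembles are seeded, complete, and explore basins", {
  quad <- function(x) sum((x - 0.3)^2)
  e1 <- multi_start_fit(quad, lower = c(-1, -1), upper = c(1, 1),
                        n_sets = 10, seed = 5, tol = 1e-8)
  e2 <- multi_start_fit(quad, lower = c(-1, -1), upper = c(1, 1),
                        n_sets = 10, seed = 5, tol = 1e-8)
  expect_identical(ensemble_params(e1), ensemble_params(e2))
  expect_length(e1$fits, 10)
  # convex objective: all sets agree
  expect_lt(max(apply(ensemble_params(e1), 1, quad)), 1e-8)

  # two-basin objective: both minima represented
  twob <- function(x) min((x + 1)^2, (x - 1)^2 + 0.05)
  e3 <- multi_start_fit(twob, lower = -2, upper = 2, n_sets = 10, seed = 2,
                        tol = 1e-8)
  mins <- round(as.numeric(ensemble_params(e3)))
  expect_setequal(unique(mins), c(-1, 1))
})

test_that("prediction consistency accepts unified ensembles and flags divergent ones", {
  mk_ens <- function(pars) {
    structure(list(fits = lapply(pars, function(p)
      structure(list(par = p, value = 0), class = "fit_result")), best = 1L),
      class = "ensemble_fit")
  }
  predict_fn <- function(par, probe) par * probe  # linear in the parameter
  probes <- list(1:5)
  same <- mk_ens(rep(list(2), 10))
  res <- prediction_consistency(same, probes, predict_fn, floor = 1e-9)
  expect_equal(res$score, 0)
  expect_true(res$accepted)

  divergent <- mk_ens(c(rep(list(2), 9), list(20)))
  res2 <- prediction_consistency(divergent, probes, predict_fn, floor = 1e-9)
  expect_false(res2$accepted)
  expect_gt(res2$score, 0.1)
  expect_true(prediction_consistency(divergent, probes, predict_fn,
                                     tolerance = Inf)$accepted)
})
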