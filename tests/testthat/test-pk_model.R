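test_that("saturable transition and degradation rates have the stated limits", {
  # linear limit (alpha = 0), saturation limit (w/alpha), direct evaluation
  expect_equal(transition_rate(3, 2, 0), 6)
  expect_equal(transition_rate(1e9, 2, 0.5), 4, tolerance = 1e-8)
  expect_equal(transition_rate(1, 1, 1), 0.5)
  expect_equal(degradation_rate(5, 3, 0), 15)
  expect_equal(degradation_rate(1e9, 3, 1.5), 2, tolerance = 1e-8)
  expect_equal(degradation_rate(2, 1, 0.5), 1)
  expect_error(transition_rate(-1, 1, 0), "non-negative")
  expect_error(degradation_rate(1, -1, 0), "non-negative")
})

test_that("route topologies have the required structure", {
  iv <- pk_topology("IV")
  expect_equal(iv$n_compartments, 4)
  expect_equal(iv$dose_compartment, iv$plasma)
  for (rt in c("SC", "IP")) {
    t8 <- pk_topology(rt)
    expect_equal(t8$n_compartments, 8)
    expect_identical(t8$labels[t8$dose_compartment], "depot")
  }
  # every compartment must be reachable from the dosed compartment
  expect_error(
    pk_topology("IV", transitions = rbind(c(1, 2), c(2, 1), c(3, 1), c(4, 1))),
    "reachable")
  # non-sequential absorption wiring is permitted
  expect_silent(pk_topology("SC", transitions = rbind(
    c(2, 3), c(3, 2), c(2, 4), c(4, 5), c(3, 5), c(5, 1), c(2, 1),
    c(1, 6), c(1, 7), c(1, 8))))
})

test_that("pk_rhs conserves mass up to degradation", {
  topo <- pk_topology("IV")
  # single enabled transition, no degradation: antisymmetric derivative pair
  t1 <- pk_topology("IV", transitions = rbind(c(1, 2), c(2, 1), c(1, 3),
                                              c(1, 4)),
                    degradations = integer(0))
  p1 <- pk_params(t1, w = c(2, 0, 0, 0), d = numeric(0), beta = numeric(0))
  rhs <- pk_rhs(c(10, 0, 0, 0), t1, p1)
  expect_equal(rhs$dx[1], -20)
  expect_equal(rhs$dx[2], 20)
  expect_equal(sum(rhs$dx), 0)
  expect_equal(rhs$degraded, 0)

  # full IV system with random positive parameters: sum(dx) == -degradation
  set.seed(11)
  p <- pk_params(topo, w = runif(6, 0.5, 10), alpha = runif(6, 0, 0.2),
                 d = runif(4, 0.5, 5), beta = runif(4, 0, 0.5))
  x <- runif(4, 0, 30)
  rhs <- pk_rhs(x, topo, p)
  expect_equal(sum(rhs$dx), -rhs$degraded, tolerance = 1e-12)
  # empty system: all derivatives zero
  expect_equal(pk_rhs(numeric(4), topo, p)$dx, numeric(4))
  # params/topology mismatch
  expect_error(pk_rhs(x, topo, p1), "one w per enabled transition")
})

test_that("plasma and tissue concentrations follow the stated conversions", {
  p <- pk_params(pk_topology("IV"), w = 1, d = 1, s = 50, V_plasma = 2)
  expect_equal(plasma_concentration(50, p), 25)
  expect_equal(plasma_concentration(0, p), 0)
  expect_equal(plasma_concentration(1, p), 0.5)
  expect_equal(tissue_concentration(25, 1), 25)
  expect_equal(tissue_concentration(25, 100), 0.25)
  expect_equal(tissue_concentration(0, 50), 0)
  expect_warning(tissue_concentration(10, 0.5), "realistic range")
  expect_warning(pk_params(pk_topology("IV"), w = 1, d = 1, s = 500),
                 "realistic range")
})

test_that("mass balance holds to 1e-6 under arbitrary regimens", {
  set.seed(21)
  for (rt in c("IV", "SC", "IP")) {
    reg <- regimen(rt, dose_ug = runif(1, 5, 100), onset_day = runif(1, 0, 2),
                   interval_days = runif(1, 0.3, 2),
                   n_doses = sample(3:12, 1))
    tr <- suppressWarnings(quick_sim(reg, t_end = 15, dt = 0.002))
    expect_lt(mass_balance_error(tr), 1e-6)
  }
})

test_that("with all saturations zero the PK system matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  topo <- pk_topology("IV")
  p <- pk_params(topo, w = c(8, 6, 5, 4, 3, 2), alpha = 0,
                 d = c(18, 4, 3, 2), beta = 0)
  tr <- simulate_therapy(bolus("IV"), list(topology = topo, params = p),
                         gt_model$pd, t_end = 1, dt = 5e-4, pd_on = FALSE,
                         thin = 100L)
  A <- pk_linear_matrix(topo, p)
  x0 <- c(50, 0, 0, 0)
  for (tt in c(0.1, 0.5, 1)) {
    oracle <- as.numeric(Matrix::expm(A * tt) %*% x0)
    got <- tr$pk[which.min(abs(tr$time - tt)), ]
    expect_equal(unname(got), oracle, tolerance = 1e-6)
  }
})

test_that("amounts stay non-negative and plasma AUC is monotone in dose", {
  for (dose in c(1, 400)) {
    tr <- quick_sim(bolus("SC", dose), t_end = 6, dt = 0.002)
    expect_gt(min(tr$pk), -1e-9)
    expect_gt(min(tr$pd), -1e-9)
  }
  auc <- vapply(c(5, 25, 50, 100, 300), function(dose) {
    tr <- quick_sim(bolus("SC", dose), t_end = 6, dt = 0.002, pd_on = FALSE)
    g <- tr$grid
    sum(diff(g$time_days) * (head(g$plasma_ug_ml, -1) + tail(g$plasma_ug_ml, -1)) / 2)
  }, numeric(1))
  expect_true(all(diff(auc) > 0))
})
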