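test_that("regimens expand to the documented bolus event lists", {
  ev <- expand_regimen(regimen("SC", 50, onset_day = 3, interval_days = 1,
                               n_doses = 16))
  expect_equal(nrow(ev), 16)
  expect_equal(ev$time_day, 3:18)
  expect_equal(sum(ev$amount_ug), 800)
  expect_true(all(ev$compartment == "depot"))

  ev2 <- expand_regimen(regimen("SC", 25, onset_day = 3, interval_days = 0.5,
                                n_doses = 32))
  expect_equal(nrow(ev2), 32)
  expect_equal(sum(ev2$amount_ug), 800)
  expect_equal(ev2$time_day[1:3], c(3, 3.5, 4))

  expect_equal(nrow(expand_regimen(pbs_regimen())), 0)
  expect_true(all(expand_regimen(bolus("IV"))$compartment == "plasma"))
})

test_that("tumor volume follows the ellipsoid diameter formula", {
  expect_equal(volume_from_diameters(0, 5), 0)
  expect_equal(volume_from_diameters(10, 10), 500)
  expect_equal(volume_from_diameters(12, 8), 384)
  expect_equal(volume_from_diameters(8, 12), 384)  # order-free
  expect_error(volume_from_diameters(-1, 2), "non-negative")
})

test_that("simulation is deterministic and starts from the injected bolus", {
  a <- quick_sim(std_regimen())
  b <- quick_sim(std_regimen())
  expect_identical(a$grid, b$grid)
  # single IV 50 ug bolus: 25 ug/ml at t = 0+, then monotone decline
  tr <- quick_sim(bolus("IV"), t_end = 3, dt = 0.002)
  expect_equal(tr$grid$plasma_ug_ml[1], 25)
  expect_true(all(diff(tr$grid$plasma_ug_ml) < 1e-9))
  # PBS control: disease-only dynamics
  ctrl <- quick_sim(pbs_regimen())
  expect_equal(ctrl$grid$tumor_mm3,
               cells_to_volume(logistic_analytic(ctrl$time, 1e5,
                                                 gt_model$pd$r, gt_model$pd$K)),
               tolerance = 1e-6)
})

test_that("splitting and resuming a simulation reproduces the whole trajectory", {
  reg <- std_regimen()
  whole <- quick_sim(reg, t_end = 20, dt = 0.004, thin = 1L)
  t_split <- 7.3
  i <- which.min(abs(whole$time - t_split))
  part1 <- suppressWarnings(quick_sim(reg, t_end = t_split, dt = 0.004,
                                      thin = 1L))
  n1 <- length(part1$time)
  pk_model <- gt_model$pk$SC
  part2 <- simulate_therapy(reg, pk_model, gt_model$pd, t_end = 20,
                            dt = 0.004, t0 = t_split,
                            init = part1$pd[n1, ],
                            init_pk = part1$pk[n1, ],
                            cum_deg0 = part1$cum_degraded[n1], thin = 1L)
  j <- length(part2$time)
  expect_equal(part2$pd[j, ], whole$pd[length(whole$time), ],
               tolerance = 1e-9)
  expect_equal(part2$pk[j, ], whole$pk[length(whole$time), ],
               tolerance = 1e-9)
})

test_that("RK4 shows fourth-order convergence on the logistic benchmark", {
  p <- gt_model$pd
  err <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    tr <- quick_sim(pbs_regimen(), t_end = 10, dt = dt)
    truth <- logistic_analytic(10, 1e5, p$r, p$K)
    abs(trajectory_at(tr, 10, "tumor_cells") - truth) / truth
  }, numeric(1))
  ratio1 <- err[1] / err[2]
  ratio2 <- err[2] / err[3]
  expect_gt(ratio1, 10)
  expect_lt(ratio1, 24)
  expect_gt(ratio2, 10)
  expect_lt(ratio2, 24)
})

test_that("halving the default step leaves the final tumor volume unchanged to 0.1%", {
  v1 <- final_volume(std_regimen(), dt = 0.002)
  v2 <- final_volume(std_regimen(), dt = 0.001)
  expect_lt(abs(v1 - v2) / v2, 0.001)
})

test_that("dose extremes bracket the response", {
  v0 <- final_volume(pbs_regimen())
  v100 <- final_volume(regimen("SC", 100, onset_day = 3, interval_days = 1,
                               n_doses = 16))
  expect_gt(v0, v100)
  expect_gt(v100, 0)
})

test_that("a route mismatch between regimen and PK model errors", {
  expect_error(
    simulate_therapy(bolus("IV"), gt_model$pk$SC, gt_model$pd, t_end = 1),
    "does not match")
})

test_that("the compiled integrator matches deSolve running the R-level right-hand sides", {
  skip_if_not_installed("deSolve")
  pk_model <- gt_model$pk$SC
  pd <- gt_model$pd
  rhs_r <- function(t, y, parms) {
    n <- pk_model$topology$n_compartments
    pk_part <- pk_rhs(y[seq_len(n)], pk_model$topology, pk_model$params)
    u <- tissue_concentration(
      plasma_concentration(max(y[1], 0), pk_model$params), pk_model$params$s)
    pd_part <- pd_rhs(y[n + 1 + seq_len(6)], u, pd)
    list(c(pk_part$dx, pk_part$degraded, pd_part))
  }
  y0 <- c(numeric(pk_model$topology$n_compartments), 0,
          pd_baseline_state(pd))
  y0[pk_model$topology$dose_compartment] <- 50  # bolus in the depot at t0
  times <- seq(0, 2, by = 0.002)
  ref <- deSolve::rk4(y0, times, rhs_r, parms = NULL)

  tr <- quick_sim(bolus("SC", 50), t_end = 2, dt = 0.002, thin = 1L)
  i <- match(c(0.5, 1, 2), tr$time)
  j <- match(c(0.5, 1, 2), times)
  expect_equal(unname(tr$pk[i, ]),
               unname(ref[j, 1 + seq_len(8)]), tolerance = 1e-8)
  expect_equal(unname(tr$pd[i, "T"]), unname(ref[j, 1 + 8 + 1 + 6]),
               tolerance = 1e-8)
})
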