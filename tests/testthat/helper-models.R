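# Shared fixtures: small models and cheap simulation settings used across
# the test files. Everything is built in code; nothing is read from disk.

# default ground-truth model, built once per test run
gt_model <- default_model("B16-early")

# a single-dose regimen per route
bolus <- function(route, dose = 50) {
  regimen(route, dose, onset_day = 0, n_doses = 1)
}

pbs_regimen <- function() regimen("SC", 0, onset_day = 3, n_doses = 0)

std_regimen <- function() {
  regimen("SC", 50, onset_day = 3, interval_days = 1, n_doses = 16)
}

# simulate with moderately coarse steps to keep the suite quick; accuracy-
# sensitive tests set their own dt
quick_sim <- function(reg, model = gt_model, t_end = 20, dt = 0.004, ...) {
  simulate_therapy(reg, model$pk[[reg$route]], model$pd, t_end = t_end,
                   dt = dt, init = pd_baseline_state(model$pd, T0 = model$T0),
                   ...)
}

final_volume <- function(reg, model = gt_model, t_end = 20, dt = 0.004) {
  trajectory_at(quick_sim(reg, model, t_end = t_end, dt = dt), t_end)
}

# dense-matrix linear ODE right-hand side of a PK system with all
# saturation constants zero; used by the matrix-exponential oracle
pk_linear_matrix <- function(topology, params) {
  n <- topology$n_compartments
  A <- matrix(0, n, n)
  tr <- topology$transitions
  for (e in seq_len(nrow(tr))) {
    A[tr$from[e], tr$from[e]] <- A[tr$from[e], tr$from[e]] - params$w[e]
    A[tr$to[e], tr$from[e]] <- A[tr$to[e], tr$from[e]] + params$w[e]
  }
  for (k in seq_along(topology$degradations)) {
    i <- topology$degradations[k]
    A[i, i] <- A[i, i] - params$d[k]
  }
  A
}
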