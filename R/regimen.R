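#' Dosing regimen
#'
#' A regimen is a route, a per-administration dose, a first-dose day, an
#' inter-dosing interval and a number of doses. The standard early-onset B16
#' schedule, for example, is 16 SC injections of 50 ug given daily from day 3
#' (800 ug total); its fractionated counterpart gives 25 ug every 12 h.
#'
#' @param route `"IV"`, `"SC"` or `"IP"`.
#' @param dose_ug dose per administration (ug).
#' @param onset_day day of the first dose (days post tumor inoculation).
#' @param interval_days inter-dosing interval (1 daily, 0.5 twice daily, ...).
#' @param n_doses number of administrations (0 gives a PBS control).
#' @param label free-text arm label.
#' @return an object of class `regimen`.
#' @export
regimen <- function(route = c("SC", "IP", "IV"), dose_ug, onset_day = 3,
                    interval_days = 1, n_doses = 1, label = NULL) {
  route <- match.arg(route)
  if (dose_ug < 0) stop("dose_ug must be >= 0")
  if (n_doses < 0) stop("n_doses must be >= 0")
  if (interval_days <= 0) stop("interval_days must be > 0")
  if (is.null(label))
    label <- sprintf("%s %g ug q%gd x%d", route, dose_ug, interval_days,
                     n_doses)
  structure(list(route = route, dose_ug = dose_ug, onset_day = onset_day,
                 interval_days = interval_days, n_doses = as.integer(n_doses),
                 label = label),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %s: %g ug %s, every %g d from day %g, %d dose(s), total %g ug\n",
              x$label, x$dose_ug, x$route, x$interval_days, x$onset_day,
              x$n_doses, x$dose_ug * x$n_doses))
  invisible(x)
}

#' Total administered dose of a regimen
#' @param x a [regimen()].
#' @return total dose in ug.
#' @export
total_dose <- function(x) x$dose_ug * x$n_doses

#' Expand a regimen to timestamped bolus events
#'
#' @param regimen a [regimen()].
#' @return data.frame with columns `time_day`, `compartment` (`"depot"` for
#'   SC/IP, `"plasma"` for IV) and `amount_ug`; zero rows for a PBS control.
#' @export
expand_regimen <- function(regimen) {
  stopifnot(inherits(regimen, "regimen"))
  n <- regimen$n_doses
  comp <- if (regimen$route == "IV") "plasma" else "depot"
  data.frame(
    time_day = regimen$onset_day + regimen$interval_days * seq_len(n) -
      regimen$interval_days,
    compartment = rep(comp, n),
    amount_ug = rep(regimen$dose_ug, n))
}

#' Tumor volume from two perpendicular diameters
#'
#' Standard murine ellipsoid approximation: `length * width^2 / 2` with
#' `length = max(d1, d2)`.
#'
#' @param d1,d2 perpendicular diameters (mm).
#' @return volume in mm3.
#' @export
volume_from_diameters <- function(d1, d2) {
  if (any(d1 < 0) || any(d2 < 0)) stop("diameters must be non-negative")
  pmax(d1, d2) * pmin(d1, d2)^2 / 2
}

#' Simulate a therapy course
#'
#' Integrates the coupled PK (4 or 8 compartments plus a cumulative
#' degradation accumulator) and PD/disease (6 states) system with fixed-step
#' classical fourth-order Runge-Kutta, applying each bolus in the expanded
#' regimen as an instantaneous amount increment (snapped to the step grid)
#' before the step. Deterministic for fixed inputs.
#'
#' @param regimen a [regimen()]; its route must match `pk$topology`.
#' @param pk list with elements `topology` ([pk_topology()]) and `params`
#'   ([pk_params()]).
#' @param pd a [pd_params()].
#' @param t_end end of simulation (days); default 20 (end of the early-onset
#'   B16 therapy window).
#' @param dt integration step (days), default 0.002.
#' @param init initial PD state, default [pd_baseline_state()].
#' @param t0 start time (days), default 0 (inoculation).
#' @param init_pk optional initial PK amounts (default: no drug on board).
#' @param cum_deg0 initial value of the degradation accumulator.
#' @param thin keep every `thin`-th step in the output grid (default 10).
#' @param pd_on integrate the PD block (set `FALSE` for pure PK runs).
#' @return an object of class `trajectory`: a list with `time` (days),
#'   `pk` (matrix of compartment amounts, ug), `cum_degraded` (ug), `pd`
#'   (matrix N, C, pN, pC, Mem, T) and a derived data.frame `grid` with
#'   columns time_days, plasma_ug_ml, tissue_ug_ml, NK, CTL, memory,
#'   tumor_cells, tumor_mm3.
#' @export
simulate_therapy <- function(regimen, pk, pd, t_end = 20, dt = 0.002,
                             init = pd_baseline_state(pd), t0 = 0,
                             init_pk = NULL, cum_deg0 = 0, thin = 10L,
                             pd_on = TRUE) {
  stopifnot(inherits(regimen, "regimen"), inherits(pd, "pd_params"))
  if (regimen$route != pk$topology$route)
    stop("regimen route (", regimen$route, ") does not match PK topology (",
         pk$topology$route, ")")
  events <- expand_regimen(regimen)
  if (nrow(events) && max(events$time_day) > t_end)
    warning("dose events beyond t_end are ignored")
  simulate_events(events, pk, pd, t0 = t0, t_end = t_end, dt = dt,
                  init = init, init_pk = init_pk, cum_deg0 = cum_deg0,
                  thin = thin, pd_on = pd_on)
}

# Shared driver: integrate given an explicit bolus-event table.
simulate_events <- function(events, pk, pd, t0, t_end, dt, init,
                            init_pk = NULL, cum_deg0 = 0, thin = 10L,
                            pd_on = TRUE) {
  args <- pk_cpp_args(pk$topology, pk$params)
  n_pk <- args$n_pk
  if (is.null(init_pk)) init_pk <- numeric(n_pk)
  # events strictly before t0 belong to an earlier segment (their drug is in
  # init_pk); events beyond t_end never fire
  keep <- events$time_day >= t0 - dt / 2 & events$time_day <= t_end + 1e-12
  out <- sim_pkpd_cpp(
    n_pk, args$edge_from, args$edge_to, args$w, args$alpha,
    args$deg_comp, args$d, args$beta, args$V_plasma, args$s_factor,
    pd_param_vector(pd), init_pk, as.numeric(init), cum_deg0,
    t0, t_end, dt,
    as.numeric(events$time_day[keep]), as.numeric(events$amount_ug[keep]),
    args$dose_comp, as.integer(thin), pd_on)
  time <- out[, 1]
  pk_amt <- out[, 1 + seq_len(n_pk), drop = FALSE]
  colnames(pk_amt) <- pk$topology$labels
  cumdeg <- out[, n_pk + 2]
  pd_mat <- out[, n_pk + 2 + seq_len(6), drop = FALSE]
  colnames(pd_mat) <- c("N", "C", "pN", "pC", "Mem", "T")
  plasma <- pk_amt[, 1] / pk$params$V_plasma
  grid <- data.frame(
    time_days = time,
    plasma_ug_ml = plasma,
    tissue_ug_ml = plasma / pk$params$s,
    NK = pd_mat[, "N"], CTL = pd_mat[, "C"], memory = pd_mat[, "Mem"],
    tumor_cells = pd_mat[, "T"],
    tumor_mm3 = cells_to_volume(pd_mat[, "T"]))
  structure(list(time = time, pk = pk_amt, cum_degraded = cumdeg,
                 pd = pd_mat, grid = grid, dt = dt,
                 events = events[keep, , drop = FALSE],
                 dosed = sum(events$amount_ug[keep]) + sum(init_pk) + cum_deg0),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d points over %.3g-%.3g d (dt = %g); final tumor %.1f mm3\n",
    length(x$time), min(x$time), max(x$time), x$dt,
    x$grid$tumor_mm3[length(x$time)]))
  invisible(x)
}

#' Interpolate a trajectory at arbitrary times
#'
#' @param traj a trajectory from [simulate_therapy()].
#' @param times days at which to evaluate.
#' @param what column of the derived grid (default `"tumor_mm3"`).
#' @return numeric vector of interpolated values.
#' @export
trajectory_at <- function(traj, times, what = "tumor_mm3") {
  stats::approx(traj$grid$time_days, traj$grid[[what]], xout = times,
                rule = 2)$y
}

#' Mass-balance residual of a trajectory
#'
#' Total injected dose minus drug on board minus cumulative degraded amount,
#' relative to the injected dose; should be zero to integration tolerance.
#'
#' @param traj a trajectory.
#' @return maximal absolute relative residual over the saved grid.
#' @export
mass_balance_error <- function(traj) {
  if (traj$dosed == 0) return(0)
  # injected-so-far at each saved time (events are snapped to the grid, so
  # compare with half-step tolerance)
  baseline <- traj$dosed - sum(traj$events$amount_ug)  # drug on board at t0
  injected <- baseline + vapply(traj$time, function(t) {
    sum(traj$events$amount_ug[traj$events$time_day <= t + traj$dt / 2])
  }, numeric(1))
  resid <- injected - rowSums(traj$pk) - traj$cum_degraded
  max(abs(resid)) / traj$dosed
}
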