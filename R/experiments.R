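#' Therapy-onset scan
#'
#' Simulates the standard daily regimen initiated on different days, keeping
#' dose, interval and therapy duration fixed, and records the tumor volume
#' at the end of each regimen's therapy window (onset + window days). The
#' default window mirrors the standard early-onset course: 16 daily doses
#' with the endpoint 17 days after onset (day 20 for the day-3 standard).
#'
#' @param onsets first-dose days to scan (default the scanned grid
#'   1, 3, 5, 8, 10).
#' @param base base [regimen()] supplying route, dose, interval, n_doses.
#' @param model model list (as from [default_model()] or a fitted
#'   `sequential_fit$model`).
#' @param window_days days from onset to the endpoint (default 17).
#' @param dt integration step.
#' @param keep_trajectories retain full trajectories per grid point.
#' @return a `scan_result`: data.frame `grid` with columns `onset_day`,
#'   `end_day`, `final_tumor_mm3`, `pct_vs_reference` (reference = onset 3
#'   if present, else the first onset).
#' @export
scan_onset <- function(onsets = c(1, 3, 5, 8, 10),
                       base = regimen("SC", 50, onset_day = 3,
                                      interval_days = 1, n_doses = 16),
                       model = default_model(), window_days = 17,
                       dt = 0.002, keep_trajectories = FALSE) {
  if (any(onsets < 1)) stop("onsets must be >= 1 day post-inoculation")
  trajs <- vector("list", length(onsets))
  finals <- numeric(length(onsets))
  for (i in seq_along(onsets)) {
    reg <- base
    reg$onset_day <- onsets[i]
    end <- onsets[i] + window_days
    tr <- simulate_therapy(reg, model$pk[[reg$route]], model$pd,
                           t_end = end, dt = dt,
                           init = pd_baseline_state(model$pd, T0 = model$T0))
    finals[i] <- trajectory_at(tr, end)
    if (keep_trajectories) trajs[[i]] <- tr
  }
  ref <- if (3 %in% onsets) finals[match(3, onsets)] else finals[1]
  grid <- data.frame(onset_day = onsets, end_day = onsets + window_days,
                     final_tumor_mm3 = finals,
                     pct_vs_reference = 100 * (1 - finals / ref))
  structure(list(scan_variable = "onset_day", grid = grid,
                 trajectories = if (keep_trajectories) trajs),
            class = "scan_result")
}

#' Iso-dose fractionation scan
#'
#' Distributes one total dose over the treatment window with different
#' per-dose intensities and inter-dosing intervals, and compares the tumor
#' volume at the common endpoint. Schemes violating the iso-dose constraint
#' are rejected.
#'
#' @param total_dose_ug total dose per course (default 800 ug, the standard
#'   16 x 50 ug course).
#' @param schemes data.frame with columns `dose_ug` and `interval_days` (or
#'   list of such pairs); default grid: intervals 72, 48, 24, 12, 6, 3 h at
#'   iso-dose 800 ug (6 x 133.3, 9 x 88.9, 16 x 50, 32 x 25, 64 x 12.5,
#'   128 x 6.25).
#' @param model model list.
#' @param onset_day first dose day (default 3).
#' @param end_day common endpoint (default 20).
#' @param dt integration step.
#' @param tol relative tolerance on the iso-dose check.
#' @return a `scan_result` with `grid` columns `dose_ug`, `interval_days`,
#'   `n_doses`, `final_tumor_mm3`, `pct_vs_reference` (reference = the
#'   24-hour scheme if present, else the coarsest interval).
#' @export
scan_fractionation <- function(total_dose_ug = 800,
                               schemes = data.frame(
                                 dose_ug = c(800 / 6, 800 / 9, 50, 25, 12.5,
                                             6.25),
                                 interval_days = c(3, 2, 1, 0.5, 0.25, 0.125)),
                               model = default_model(), onset_day = 3,
                               end_day = 20, dt = 0.002, tol = 1e-9) {
  schemes <- as.data.frame(schemes)
  n_doses <- total_dose_ug / schemes$dose_ug
  bad <- abs(n_doses - round(n_doses)) > tol
  if (any(bad))
    stop("scheme(s) violate the iso-dose constraint: dose ",
         paste(schemes$dose_ug[bad], collapse = ", "),
         " ug does not divide the total dose ", total_dose_ug, " ug")
  n_doses <- as.integer(round(n_doses))
  span <- (n_doses - 1) * schemes$interval_days
  if (any(onset_day + span > end_day + tol))
    stop("scheme(s) do not fit the treatment window ending at day ", end_day)
  finals <- numeric(nrow(schemes))
  for (i in seq_len(nrow(schemes))) {
    reg <- regimen("SC", schemes$dose_ug[i], onset_day = onset_day,
                   interval_days = schemes$interval_days[i],
                   n_doses = n_doses[i])
    tr <- simulate_therapy(reg, model$pk$SC, model$pd, t_end = end_day,
                           dt = dt,
                           init = pd_baseline_state(model$pd, T0 = model$T0))
    finals[i] <- trajectory_at(tr, end_day)
  }
  ref_i <- if (any(schemes$interval_days == 1)) which(schemes$interval_days == 1)[1]
           else which.max(schemes$interval_days)
  grid <- data.frame(dose_ug = schemes$dose_ug,
                     interval_days = schemes$interval_days,
                     n_doses = n_doses, final_tumor_mm3 = finals,
                     pct_vs_reference = 100 * (1 - finals / finals[ref_i]))
  structure(list(scan_variable = "fractionation", grid = grid,
                 end_day = end_day, total_dose_ug = total_dose_ug),
            class = "scan_result")
}

#' Daily-dose titration scan
#'
#' Simulates once-daily regimens over the standard window under different
#' dose intensities, including dose 0 as the control anchor.
#'
#' @param daily_doses_ug doses to scan (default 0.5-100 ug plus 0).
#' @param model model list.
#' @param onset_day,end_day therapy window (default days 3-20, 16 doses).
#' @param n_doses doses per course (default 16).
#' @param dt integration step.
#' @return a `scan_result` with `grid` columns `daily_dose_ug`,
#'   `final_tumor_mm3`, `pct_vs_reference` (reference = dose 0).
#' @export
scan_dose <- function(daily_doses_ug = c(0, 0.5, 1, 2, 5, 12, 25, 50, 100),
                      model = default_model(), onset_day = 3, end_day = 20,
                      n_doses = 16, dt = 0.002) {
  if (any(daily_doses_ug < 0)) stop("doses must be >= 0")
  if (!0 %in% daily_doses_ug) daily_doses_ug <- c(0, daily_doses_ug)
  finals <- vapply(daily_doses_ug, function(dd) {
    reg <- regimen("SC", dd, onset_day = onset_day, interval_days = 1,
                   n_doses = if (dd > 0) n_doses else 0L)
    tr <- simulate_therapy(reg, model$pk$SC, model$pd, t_end = end_day,
                           dt = dt,
                           init = pd_baseline_state(model$pd, T0 = model$T0))
    trajectory_at(tr, end_day)
  }, numeric(1))
  ref <- finals[daily_doses_ug == 0][1]
  grid <- data.frame(daily_dose_ug = daily_doses_ug,
                     final_tumor_mm3 = finals,
                     pct_vs_reference = 100 * (1 - finals / ref))
  structure(list(scan_variable = "daily_dose_ug", grid = grid,
                 end_day = end_day),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> over", x$scan_variable, "\n")
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Percent difference between two scan endpoints
#'
#' `100 * (1 - A/B)`: the percent by which outcome A lies below reference
#' B (positive when A is the better, i.e. smaller, tumor).
#'
#' @param a,b final tumor volumes (same endpoint day).
#' @return percent difference.
#' @export
endpoint_ratio <- function(a, b) {
  if (b == 0) stop("undefined ratio: reference endpoint is zero")
  100 * (1 - a / b)
}

#' Two-sample endpoint comparison
#'
#' Student's t-test, two-tailed, assuming equal variance (pooled), as used
#' for comparing cohort endpoints; only meaningful for synthetic cohorts
#' carrying animal-level noise, never for deterministic trajectories.
#'
#' @param group_a,group_b endpoint volumes per animal (n >= 2 each).
#' @return list with `t`, `p`, `df`.
#' @export
t_test_endpoints <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs n >= 2")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("degenerate test: zero pooled variance")
  ht <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}
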