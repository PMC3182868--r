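#' Measurement noise model for virtual cohorts
#'
#' @param proportional_cv coefficient of variation of multiplicative
#'   measurement noise (fraction; default 0.10).
#' @param additive_sd additive noise SD (mm3 for tumor, ug/ml for PK).
#' @param floor_at_zero truncate negative measurements at zero.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(proportional_cv = 0.10, additive_sd = 0,
                        floor_at_zero = TRUE) {
  if (proportional_cv < 0 || additive_sd < 0)
    stop("noise magnitudes must be >= 0")
  structure(list(proportional_cv = proportional_cv,
                 additive_sd = additive_sd,
                 floor_at_zero = floor_at_zero),
            class = "noise_model")
}

apply_noise <- function(values, noise) {
  out <- values * (1 + rnorm(length(values), 0, noise$proportional_cv)) +
    rnorm(length(values), 0, noise$additive_sd)
  if (noise$floor_at_zero) out <- pmax(out, 0)
  out
}

#' Generate a synthetic single-dose PK profile
#'
#' Simulates one bolus through the PK model, samples the plasma
#' concentration at the requested times for each virtual animal with seeded
#' measurement noise, and aggregates to cohort mean and SEM.
#'
#' @param route `"IV"`, `"SC"` or `"IP"`.
#' @param dose_ug administered dose (default 50 ug, the training setting).
#' @param sampling_times observation times (days after dosing).
#' @param pk_model list with `topology` and `params` (the ground truth).
#' @param noise a [noise_model()].
#' @param n_mice virtual animals (default 6).
#' @param seed integer seed.
#' @param dt integration step (days).
#' @return a [ts_dataset()] of serum concentrations (ug/ml), with the
#'   noise-free curve in attribute `"truth"`.
#' @export
generate_pk_profiles <- function(route, dose_ug = 50,
                                 sampling_times = c(0.04, 0.08, 0.17, 0.25,
                                                    0.5, 0.75, 1, 1.5, 2, 3),
                                 pk_model = default_pk_model(route),
                                 noise = noise_model(), n_mice = 6,
                                 seed = 1, dt = 0.002) {
  if (dose_ug <= 0) stop("dose_ug must be positive")
  reg <- regimen(route, dose_ug, onset_day = 0, n_doses = 1)
  traj <- simulate_therapy(reg, pk_model, default_pd_params(),
                           t_end = max(sampling_times), dt = dt,
                           pd_on = FALSE)
  truth <- trajectory_at(traj, sampling_times, "plasma_ug_ml")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  obs <- replicate(n_mice, apply_noise(truth, noise))
  out <- ts_dataset(sampling_times, rowMeans(obs),
                    sem = apply(obs, 1, sd) / sqrt(n_mice), n = n_mice,
                    arm = paste0("PK-", route))
  attr(out, "truth") <- truth
  out
}

#' Cohort specification for the tumor-volume generator
#'
#' @param tumor_type `"B16"` or `"RenCa"` (informational label).
#' @param regimen a [regimen()].
#' @param n_mice animals in the cohort.
#' @param measurement_days caliper measurement schedule (about 3x/week).
#' @param noise a [noise_model()] for measurement noise.
#' @param neutralization `"none"`, `"NK"` (k1 = 0) or `"Tcell"` (k2 = 0).
#' @param animal_cv lognormal coefficient of variation of the per-animal
#'   growth-rate multiplier (default 0.15).
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(tumor_type = "B16", regimen, n_mice = 6,
                        measurement_days = c(3, 6, 8, 10, 13, 15, 17, 20),
                        noise = noise_model(),
                        neutralization = c("none", "NK", "Tcell"),
                        animal_cv = 0.15, seed = 1) {
  neutralization <- match.arg(neutralization)
  if (n_mice < 1) stop("n_mice must be >= 1")
  if (any(diff(measurement_days) <= 0))
    stop("measurement_days must be strictly increasing")
  structure(list(tumor_type = tumor_type, regimen = regimen, n_mice = n_mice,
                 measurement_days = measurement_days, noise = noise,
                 neutralization = neutralization, animal_cv = animal_cv,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a virtual tumor-volume cohort
#'
#' Each virtual animal follows the model trajectory under a seeded
#' animal-level lognormal growth-rate multiplier, observed with measurement
#' noise about 3x/week. An animal is euthanized - and its later time points
#' censored from the cohort mean/SEM - once its measured volume reaches the
#' 1000 mm3 threshold (the triggering measurement is the animal's last).
#' Neutralization arms simulate with `k2 = 0` (T-cell) or `k1 = 0` (NK).
#'
#' @param spec a [cohort_spec()].
#' @param model ground-truth model as from [default_model()].
#' @param dt integration step (days).
#' @param euthanasia_mm3 censoring threshold (default 1000 mm3).
#' @return a [ts_dataset()] of mean tumor volume (mm3) with per-time `n` of
#'   surviving animals; per-animal measurements in attribute `"animals"`
#'   (matrix, NA after censoring) and the noise-free mean in `"truth"`.
#' @export
generate_tumor_cohort <- function(spec, model = default_model(), dt = 0.004,
                                  euthanasia_mm3 = 1000) {
  stopifnot(inherits(spec, "cohort_spec"))
  pd <- model$pd
  if (spec$neutralization == "NK") pd$k1 <- 0
  if (spec$neutralization == "Tcell") pd$k2 <- 0
  pk <- model$pk[[spec$regimen$route]]
  t_end <- max(spec$measurement_days)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$animal_cv^2))
  mult <- rlnorm(spec$n_mice, -sdlog^2 / 2, sdlog)

  truth_traj <- simulate_therapy(spec$regimen, pk, pd, t_end = t_end, dt = dt,
                                 init = pd_baseline_state(pd, T0 = model$T0))
  truth <- trajectory_at(truth_traj, spec$measurement_days)

  obs <- matrix(NA_real_, nrow = length(spec$measurement_days),
                ncol = spec$n_mice)
  for (a in seq_len(spec$n_mice)) {
    pda <- pd
    pda$r <- pd$r * mult[a]
    traj <- simulate_therapy(spec$regimen, pk, pda, t_end = t_end, dt = dt,
                             init = pd_baseline_state(pda, T0 = model$T0))
    vol <- trajectory_at(traj, spec$measurement_days)
    meas <- apply_noise(vol, spec$noise)
    hit <- which(meas >= euthanasia_mm3)
    if (length(hit)) meas[seq_along(meas) > hit[1]] <- NA
    obs[, a] <- meas
  }
  n_surv <- rowSums(!is.na(obs))
  if (sum(n_surv > 0) < 2)
    warning("degenerate cohort: nearly all animals censored before the ",
            "second measurement")
  means <- rowMeans(obs, na.rm = TRUE)
  sems <- apply(obs, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  })
  keep <- n_surv > 0
  out <- ts_dataset(spec$measurement_days[keep], means[keep],
                    sem = sems[keep], n = pmax(n_surv[keep], 1),
                    arm = paste(spec$tumor_type, spec$regimen$label,
                                spec$neutralization))
  attr(out, "animals") <- obs
  attr(out, "truth") <- truth
  attr(out, "regimen") <- spec$regimen
  out
}

#' Build the full synthetic training/validation bundle
#'
#' Emits every dataset class the sequential calibration protocol consumes,
#' generated from a known ground-truth model: single-dose serum PK profiles
#' for the three routes, a PBS control cohort, T-cell- and NK-neutralized
#' treated cohorts, and early-onset treated cohorts (SC and IP) as training
#' data; a fractionated arm, a low-dose arm and a late-onset arm as held-out
#' validation. A manifest records every seed and ground-truth value, so the
#' bundle regenerates identically.
#'
#' @param ground_truth model list as from [default_model()].
#' @param seed master integer seed; arm seeds are derived deterministically.
#' @param measurement_cv proportional measurement noise CV (default 0.10).
#' @param animal_cv animal-level growth-rate CV (default 0.15).
#' @param n_mice animals per tumor cohort (default 8).
#' @param n_mice_pk animals per PK profile (default 6).
#' @return a list of class `training_bundle` with elements `pk_profiles`,
#'   `tumor` (named [ts_dataset()]s), `validation`, and `manifest`.
#' @export
make_training_bundle <- function(ground_truth = default_model(), seed = 1,
                                 measurement_cv = 0.10, animal_cv = 0.15,
                                 n_mice = 8, n_mice_pk = 6) {
  nm <- noise_model(proportional_cv = measurement_cv)
  seeds <- seed + seq_len(20) * 1000L
  routes <- c("IV", "SC", "IP")
  pk_profiles <- lapply(seq_along(routes), function(i) {
    generate_pk_profiles(routes[i], pk_model = ground_truth$pk[[routes[i]]],
                         noise = nm, n_mice = n_mice_pk, seed = seeds[i])
  })
  names(pk_profiles) <- routes

  std_sc <- regimen("SC", 50, onset_day = 3, interval_days = 1, n_doses = 16,
                    label = "50ug daily SC early")
  std_ip <- regimen("IP", 50, onset_day = 3, interval_days = 1, n_doses = 16,
                    label = "50ug daily IP early")
  pbs <- regimen("SC", 0, onset_day = 3, n_doses = 0, label = "PBS")
  arm <- function(reg, neut, sd, days = c(3, 6, 8, 10, 13, 15, 17, 20))
    generate_tumor_cohort(
      cohort_spec("B16", reg, n_mice = n_mice, measurement_days = days,
                  noise = nm, neutralization = neut, animal_cv = animal_cv,
                  seed = sd),
      model = ground_truth)
  tumor <- list(
    pbs = arm(pbs, "none", seeds[4]),
    tcell_neut = arm(std_sc, "Tcell", seeds[5]),
    nk_neut = arm(std_sc, "NK", seeds[6]),
    treated_SC = arm(std_sc, "none", seeds[7]),
    treated_IP = arm(std_ip, "none", seeds[8]))

  frac <- regimen("SC", 25, onset_day = 3, interval_days = 0.5, n_doses = 32,
                  label = "25ug q12h SC")
  lowd <- regimen("SC", 12, onset_day = 3, interval_days = 1, n_doses = 16,
                  label = "12ug daily SC")
  late <- regimen("SC", 50, onset_day = 8, interval_days = 1, n_doses = 16,
                  label = "50ug daily SC late")
  validation <- list(
    frac_SC = arm(frac, "none", seeds[9]),
    lowdose_SC = arm(lowd, "none", seeds[10]),
    late_SC = arm(late, "none", seeds[11],
                  days = c(8, 10, 13, 15, 17, 20, 22, 24)))

  manifest <- list(seed = seed, arm_seeds = seeds,
                   measurement_cv = measurement_cv, animal_cv = animal_cv,
                   n_mice = n_mice, n_mice_pk = n_mice_pk,
                   ground_truth = ground_truth)
  # calibration inputs that are treated as known: immune rate constants
  # (from the prior tissue model), the inoculum, and the PK structures
  fixed <- list(pd = ground_truth$pd, T0 = ground_truth$T0,
                topologies = lapply(ground_truth$pk, `[[`, "topology"))
  structure(list(pk_profiles = pk_profiles, pk_dose_ug = 50, tumor = tumor,
                 validation = validation, fixed = fixed,
                 manifest = manifest),
            class = "training_bundle")
}
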