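test_that("noise-free PK profiles reproduce the simulated concentrations", {
  quiet <- noise_model(proportional_cv = 0)
  ds <- generate_pk_profiles("IV", noise = quiet, seed = 3, dt = 0.004)
  expect_equal(ds$mean, attr(ds, "truth"))
  expect_equal(ds$sem, rep(0, nrow(ds)))
  # 50 ug into 2 ml plasma: ~25 ug/ml just after an IV bolus
  early <- generate_pk_profiles("IV", sampling_times = c(5e-4, 0.1),
                                noise = quiet, seed = 3, dt = 5e-4)
  expect_equal(early$mean[1], 25, tolerance = 0.03)
})

test_that("PK profile generation is a pure function of the seed", {
  a <- generate_pk_profiles("SC", seed = 42, dt = 0.004)
  b <- generate_pk_profiles("SC", seed = 42, dt = 0.004)
  expect_identical(a, b)
  c <- generate_pk_profiles("SC", seed = 43, dt = 0.004)
  expect_false(identical(a$mean, c$mean))
})

test_that("PBS cohorts follow the logistic control curve and censor at 1000 mm3", {
  spec <- cohort_spec("B16", pbs_regimen(), n_mice = 4,
                      measurement_days = c(3, 6, 8, 10, 13, 15, 17, 20),
                      noise = noise_model(proportional_cv = 0),
                      animal_cv = 0, seed = 9)
  ds <- generate_tumor_cohort(spec, gt_model)
  expected <- cells_to_volume(
    logistic_analytic(ds$times, 1e5, gt_model$pd$r, gt_model$pd$K))
  expect_equal(ds$mean, expected, tolerance = 1e-4)
  # the logistic control passes 1000 mm3 before day 20, so late points are
  # censored out of the cohort
  expect_lt(max(ds$times), 20)
  # only the euthanasia-triggering measurement may exceed the threshold
  expect_true(all(ds$mean[-nrow(ds)] < 1000))
})

test_that("censoring removes all post-threshold measurements from the cohort", {
  spec <- cohort_spec("B16", pbs_regimen(), n_mice = 12,
                      noise = noise_model(proportional_cv = 0.1),
                      animal_cv = 0.15, seed = 4)
  ds <- generate_tumor_cohort(spec, gt_model)
  obs <- attr(ds, "animals")
  for (a in seq_len(ncol(obs))) {
    hits <- which(obs[, a] >= 1000)
    if (length(hits) && hits[1] < nrow(obs))
      expect_true(all(is.na(obs[seq(hits[1] + 1, nrow(obs)), a])))
  }
  # reported n equals surviving animals
  expect_equal(ds$n, rowSums(!is.na(obs))[rowSums(!is.na(obs)) > 0])
  # SEM equals SD/sqrt(n) of surviving animals
  i <- which(ds$n > 1)[1]
  row <- obs[i, !is.na(obs[i, ])]
  expect_equal(ds$sem[i], sd(row) / sqrt(length(row)))
})

test_that("neutralized arms carry more tumor than the fully armed cohort", {
  mk <- function(neut) {
    spec <- cohort_spec("B16", std_regimen(), n_mice = 3,
                        noise = noise_model(proportional_cv = 0),
                        neutralization = neut, animal_cv = 0, seed = 5)
    generate_tumor_cohort(spec, gt_model)
  }
  full <- mk("none")
  nk <- mk("NK")
  tc <- mk("Tcell")
  shared <- intersect(full$times, intersect(nk$times, tc$times))
  at <- function(ds) ds$mean[match(shared, ds$times)]
  expect_true(all(at(nk) >= at(full) - 1e-9))
  expect_true(all(at(tc) >= at(full) - 1e-9))
  # CTL dominance: losing T cells costs more than losing NK cells
  expect_gt(max(at(tc)), max(at(nk)))
})

test_that("empirical cohort noise converges to the nominal level", {
  quiet <- noise_model(proportional_cv = 0.1)
  ds <- generate_pk_profiles("IV", sampling_times = c(0.1, 0.5, 1),
                             noise = quiet, n_mice = 1000, seed = 8,
                             dt = 0.004)
  truth <- attr(ds, "truth")
  # SEM at n = 1000 should approximate cv * truth / sqrt(n) within chi2-ish
  # sampling error (~5% relative at this n)
  expect_equal(ds$sem, 0.1 * truth / sqrt(1000), tolerance = 0.1)
})

test_that("the training bundle regenerates identically from its manifest", {
  b1 <- make_training_bundle(seed = 77, n_mice = 3, n_mice_pk = 3)
  m <- b1$manifest
  b2 <- make_training_bundle(ground_truth = m$ground_truth, seed = m$seed,
                             measurement_cv = m$measurement_cv,
                             animal_cv = m$animal_cv, n_mice = m$n_mice,
                             n_mice_pk = m$n_mice_pk)
  expect_identical(b1$pk_profiles, b2$pk_profiles)
  expect_identical(b1$tumor, b2$tumor)
  expect_identical(b1$validation, b2$validation)
  # bundle has every arm the calibration stages need
  expect_setequal(names(b1$tumor),
                  c("pbs", "tcell_neut", "nk_neut", "treated_SC", "treated_IP"))
  expect_named(b1$pk_profiles, c("IV", "SC", "IP"))
  # CTL-dominant ground truth: the T-cell-neutralized arm ends larger
  tn <- b1$tumor$tcell_neut
  nn <- b1$tumor$nk_neut
  expect_gt(tail(tn$mean, 1), tail(nn$mean[nn$times <= max(tn$times)], 1) * 0.9)
})
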