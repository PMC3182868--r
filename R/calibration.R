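#' Time-series dataset
#'
#' The universal container for training/validation data: cohort means with
#' SEM and group size at strictly increasing observation times. Units are
#' ug/ml for serum PK profiles and mm3 for tumor volumes.
#'
#' @param times observation times (days), strictly increasing.
#' @param mean observed cohort means.
#' @param sem standard errors of the mean (>= 0).
#' @param n animals contributing per time point (>= 1).
#' @param arm arm label (route / treatment / neutralization / control).
#' @return an object of class `ts_dataset` (a data.frame).
#' @export
ts_dataset <- function(times, mean, sem = 0, n = 1, arm = "") {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(sem < 0)) stop("sem must be >= 0")
  if (any(n < 1)) stop("n must be >= 1")
  out <- data.frame(times = times, mean = mean,
                    sem = rep_len(sem, length(times)),
                    n = rep_len(n, length(times)))
  attr(out, "arm") <- arm
  class(out) <- c("ts_dataset", "data.frame")
  out
}

#' Least-squares objective over one or more datasets
#'
#' Sum over datasets and observation times of squared prediction residuals.
#' Residuals are unweighted raw-scale differences by default; set
#' `weight_sem = TRUE` for 1/SEM^2 weighting. A failed simulation maps to a
#' large finite penalty so the pattern search can continue.
#'
#' @param params parameter vector handed to `simulator`.
#' @param datasets a `ts_dataset` or list of them.
#' @param simulator `function(params, dataset)` returning predictions at
#'   `dataset$times`.
#' @param weight_sem use 1/SEM^2 weights; each SEM is floored at
#'   `sem_floor` times the dataset's maximal mean so that near-zero tail
#'   observations cannot dominate the objective.
#' @param sem_floor relative SEM floor (default 0.005).
#' @param penalty value returned on simulation failure.
#' @return scalar sum of squares (>= 0).
#' @export
sse_objective <- function(params, datasets, simulator, weight_sem = FALSE,
                          sem_floor = 0.005, penalty = 1e12) {
  if (inherits(datasets, "ts_dataset")) datasets <- list(datasets)
  total <- 0
  for (ds in datasets) {
    pred <- tryCatch(simulator(params, ds), error = function(e) NULL)
    if (is.null(pred) || length(pred) != nrow(ds) || any(!is.finite(pred)))
      return(penalty)
    res2 <- (pred - ds$mean)^2
    if (weight_sem) {
      w <- pmax(ds$sem, sem_floor * max(abs(ds$mean)))
      if (all(w == 0)) w <- rep(1, length(w))
      res2 <- res2 / w^2
    }
    total <- total + sum(res2)
  }
  total
}

#' Coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot` with the total sum of squares taken about the
#' observed mean. Can be negative for fits worse than the mean; equals 1 for
#' a perfect fit.
#'
#' @param obs observed values (>= 2, with nonzero variance).
#' @param pred predicted values.
#' @return scalar <= 1.
#' @export
r_squared <- function(obs, pred) {
  if (length(obs) < 2) stop("need at least 2 observations")
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("R^2 undefined: observations have zero variance")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Hooke-Jeeves pattern search
#'
#' Derivative-free minimization alternating exploratory coordinate moves and
#' pattern (extrapolation) moves, halving the step sizes when no exploratory
#' move improves the objective. Terminates when every step is below `tol` or
#' the evaluation budget is exhausted. The search never leaves the bounds
#' and never accepts an increase of the objective, so the returned point is
#' at least as good as the start.
#'
#' @param objective `function(x) -> scalar`; must be finite at `x0`.
#' @param x0 start vector (inside the bounds).
#' @param steps initial step sizes (recycled; default 10% of bound range).
#' @param lower,upper bounds (recycled).
#' @param tol step-size termination tolerance.
#' @param max_evals evaluation budget.
#' @return a `fit_result` list: `par`, `value` (objective), `n_evals`,
#'   `converged`.
#' @export
hooke_jeeves <- function(objective, x0, steps = NULL,
                         lower = -Inf, upper = Inf,
                         tol = 1e-6, max_evals = 5000) {
  n <- length(x0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(x0 < lower) || any(x0 > upper)) stop("x0 outside bounds")
  if (is.null(steps)) {
    rng <- upper - lower
    steps <- ifelse(is.finite(rng), 0.1 * rng, pmax(0.1 * abs(x0), 0.1))
  }
  steps <- rep_len(steps, n)
  n_evals <- 0L
  f <- function(x) {
    n_evals <<- n_evals + 1L
    objective(x)
  }
  clamp <- function(x) pmin(pmax(x, lower), upper)
  fx <- f(x0)
  if (!is.finite(fx)) stop("objective not finite at x0")

  explore <- function(x, fx) {
    for (i in seq_len(n)) {
      for (dir in c(1, -1)) {
        xt <- x
        xt[i] <- min(max(x[i] + dir * steps[i], lower[i]), upper[i])
        if (xt[i] == x[i]) next
        ft <- f(xt)
        if (ft < fx) {
          x <- xt
          fx <- ft
          break
        }
      }
      if (n_evals >= max_evals) break
    }
    list(x = x, fx = fx)
  }

  x <- x0
  repeat {
    ex <- explore(x, fx)
    if (ex$fx < fx) {
      # pattern moves: extrapolate through the improved point, explore
      # around the extrapolation, accept only strict improvements
      prev <- x
      x <- ex$x
      fx <- ex$fx
      # chain pattern moves while they make material progress; marginal
      # (sub-machine-precision-scale) gains fall back to step halving
      while (n_evals < max_evals) {
        xp <- clamp(x + (x - prev))
        fp <- f(xp)
        ex2 <- explore(xp, fp)
        if (ex2$fx < fx - 1e-12 * (1 + abs(fx))) {
          prev <- x
          x <- ex2$x
          fx <- ex2$fx
        } else break
      }
    } else {
      steps <- steps / 2
    }
    if (all(steps < tol) || n_evals >= max_evals) break
  }
  structure(list(par = x, value = fx, n_evals = n_evals,
                 converged = all(steps < tol)),
            class = "fit_result")
}

#' Multi-start ensemble fit
#'
#' Runs `n_sets` independent Hooke-Jeeves searches from seeded
#' Latin-hypercube starting points and retains every fitted set (not just
#' the best), following the multiple-modeling principle that predictions
#' should not hinge on a single parameter vector.
#'
#' @param objective `function(x) -> scalar`.
#' @param lower,upper box bounds defining the start-sampling region.
#' @param n_sets ensemble size (default 10).
#' @param seed integer seed controlling the Latin-hypercube draw.
#' @param ... passed on to [hooke_jeeves()] (`tol`, `max_evals`, `steps`).
#' @return an `ensemble_fit`: list of `fit_result`s sorted as drawn, with
#'   the best-SSE index in `$best`.
#' @export
multi_start_fit <- function(objective, lower, upper, n_sets = 10,
                            seed = 1, ...) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  n <- length(lower)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  U <- lhs::randomLHS(n_sets, n)
  fits <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    x0 <- lower + U[i, ] * (upper - lower)
    fits[[i]] <- tryCatch(
      hooke_jeeves(objective, x0, lower = lower, upper = upper, ...),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) fits[[i]]$seed <- seed + i - 1L
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (sum(ok) < n_sets)
    stop("ensemble incomplete: only ", sum(ok), " of ", n_sets,
         " fits succeeded")
  structure(list(fits = fits,
                 best = which.min(vapply(fits, `[[`, numeric(1), "value"))),
            class = "ensemble_fit")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Ensemble parameters as a matrix
#' @param ensemble an `ensemble_fit`.
#' @return matrix with one row per fitted set.
#' @export
ensemble_params <- function(ensemble) {
  do.call(rbind, lapply(ensemble$fits, `[[`, "par"))
}

#' Prediction-consistency acceptance of an ensemble
#'
#' A calibrated model is deemed reliable only when the predictions generated
#' under all its parameter sets are unified across every probed therapeutic
#' scenario. The score is the maximum, over probe scenarios and prediction
#' times, of the pairwise relative deviation between predicted trajectories;
#' the ensemble is accepted when the score does not exceed `tolerance`.
#'
#' @param ensemble an `ensemble_fit` (>= 2 fits).
#' @param probes list of probe scenarios (typically [regimen()]s).
#' @param predict_fn `function(par, probe) -> numeric vector` of predictions
#'   (e.g. tumor volume at a fixed time grid).
#' @param tolerance maximal accepted relative deviation (default 0.1).
#' @param floor denominator floor guarding the relative deviation against
#'   near-zero predictions (units of the prediction; default 1).
#' @return list with `score`, `accepted`, and the per-probe scores.
#' @export
prediction_consistency <- function(ensemble, probes, predict_fn,
                                   tolerance = 0.1, floor = 1) {
  stopifnot(length(ensemble$fits) >= 2, length(probes) >= 1)
  per_probe <- vapply(probes, function(pr) {
    preds <- lapply(ensemble$fits, function(f) predict_fn(f$par, pr))
    m <- do.call(rbind, preds)
    worst <- 0
    for (i in seq_len(nrow(m) - 1)) for (j in seq(i + 1, nrow(m))) {
      denom <- pmax((abs(m[i, ]) + abs(m[j, ])) / 2, floor)
      worst <- max(worst, max(abs(m[i, ] - m[j, ]) / denom))
    }
    worst
  }, numeric(1))
  score <- max(per_probe)
  list(score = score, accepted = score <= tolerance, per_probe = per_probe)
}
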