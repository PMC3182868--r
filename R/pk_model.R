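#' Multi-compartment PK topology for a given administration route
#'
#' Builds the compartment graph of the semi-physiological IL-21 PK model.
#' Intravenous (IV) dosing uses a 4-compartment structure: plasma exchanging
#' drug bidirectionally with three secondary tissues (illustratively liver,
#' kidneys, bile), each of which may also degrade drug. Subcutaneous (SC) and
#' intraperitoneal (IP) dosing use an 8-compartment structure: an
#' administration-site depot feeding plasma through up to three absorption
#' compartments (a sequential chain plus a direct depot-to-plasma shortcut by
#' default; any pair among depot/absorption/plasma may be enabled), with the
#' same three secondary compartments on the elimination side.
#'
#' Compartment 1 is always plasma. For SC/IP, compartment 2 is the depot,
#' 3-5 the absorption compartments, 6-8 the secondary compartments; for IV,
#' 2-4 are the secondary compartments.
#'
#' @param route one of `"IV"`, `"SC"`, `"IP"`.
#' @param transitions optional two-column matrix/data.frame of compartment
#'   index pairs (from, to) overriding the default wiring.
#' @param degradations optional integer vector of compartments allowed to
#'   degrade drug (default: plasma and the three secondary compartments).
#' @return an object of class `pk_topology`.
#' @export
pk_topology <- function(route = c("IV", "SC", "IP"),
                        transitions = NULL, degradations = NULL) {
  route <- match.arg(route)
  if (route == "IV") {
    labels <- c("plasma", "sec1", "sec2", "sec3")
    default_tr <- rbind(
      c(1L, 2L), c(2L, 1L), c(1L, 3L), c(3L, 1L), c(1L, 4L), c(4L, 1L))
    default_deg <- c(1L, 2L, 3L, 4L)
    dose_comp <- 1L
  } else {
    labels <- c("plasma", "depot", "abs1", "abs2", "abs3",
                "sec1", "sec2", "sec3")
    default_tr <- rbind(
      c(2L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 1L),  # absorption chain
      c(2L, 1L),                                   # depot -> plasma shortcut
      c(1L, 6L), c(6L, 1L), c(1L, 7L), c(7L, 1L), c(1L, 8L), c(8L, 1L))
    default_deg <- c(1L, 6L, 7L, 8L)
    dose_comp <- 2L
  }
  n <- length(labels)
  tr <- if (is.null(transitions)) default_tr else as.matrix(transitions)
  storage.mode(tr) <- "integer"
  if (ncol(tr) != 2L) stop("transitions must have two columns (from, to)")
  if (any(tr < 1L) || any(tr > n)) stop("transition indices out of range")
  if (any(tr[, 1] == tr[, 2])) stop("self-transitions are not allowed")
  deg <- if (is.null(degradations)) default_deg else as.integer(degradations)
  if (any(deg < 1L) || any(deg > n)) stop("degradation indices out of range")

  topo <- structure(list(
    route = route, n_compartments = n, labels = labels,
    transitions = data.frame(from = tr[, 1], to = tr[, 2]),
    degradations = deg, dose_compartment = dose_comp, plasma = 1L),
    class = "pk_topology")
  if (!all(reachable_from(topo, dose_comp)))
    stop("every compartment must be reachable from the dosed compartment")
  topo
}

# breadth-first reachability over enabled transitions
reachable_from <- function(topology, start) {
  n <- topology$n_compartments
  seen <- logical(n)
  seen[start] <- TRUE
  queue <- start
  tr <- topology$transitions
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    nxt <- tr$to[tr$from == i]
    new <- nxt[!seen[nxt]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  seen
}

#' PK parameter set for a topology
#'
#' @param topology a [pk_topology()].
#' @param w,alpha transition rate (1/day) and saturation (1/ug) constants,
#'   one per enabled transition (recycled if scalar).
#' @param d,beta degradation rate (1/day) and saturation (1/ug) constants,
#'   one per degrading compartment.
#' @param s plasma:tissue correlation factor (dimensionless, realistic range
#'   1-100); tissue concentration is plasma concentration divided by `s`.
#' @param V_plasma plasma volume in ml (default 2 ml, the murine setting).
#' @return an object of class `pk_params`.
#' @export
pk_params <- function(topology, w, alpha = 0, d, beta = 0,
                      s = 10, V_plasma = 2) {
  stopifnot(inherits(topology, "pk_topology"))
  n_tr <- nrow(topology$transitions)
  n_dg <- length(topology$degradations)
  w <- rep_len(as.numeric(w), n_tr)
  alpha <- rep_len(as.numeric(alpha), n_tr)
  d <- rep_len(as.numeric(d), n_dg)
  beta <- rep_len(as.numeric(beta), n_dg)
  if (any(c(w, alpha, d, beta) < 0))
    stop("all rate and saturation constants must be >= 0")
  if (V_plasma <= 0) stop("V_plasma must be positive")
  if (s < 1 || s > 100)
    warning("s = ", s, " is outside the realistic range [1, 100]")
  structure(list(w = w, alpha = alpha, d = d, beta = beta,
                 s = s, V_plasma = V_plasma),
            class = "pk_params")
}

#' Saturable inter-compartment transition rate
#'
#' Flow of drug out of a compartment holding amount `x_i`, Michaelis-Menten
#' limited: `J = w * x_i / (1 + alpha * x_i)`. With `alpha = 0` this reduces
#' to linear first-order transport `w * x_i`; for large amounts it saturates
#' at `w / alpha`.
#'
#' @param x_i drug amount in the source compartment (ug).
#' @param w rate constant (1/day).
#' @param alpha saturation constant (1/ug).
#' @return flow in ug/day.
#' @export
transition_rate <- function(x_i, w, alpha = 0) {
  if (any(x_i < 0) || any(w < 0) || any(alpha < 0))
    stop("transition_rate: inputs must be non-negative")
  w * x_i / (1 + alpha * x_i)
}

#' Saturable degradation rate
#'
#' Drug loss from a compartment: `D = d * x_i / (1 + beta * x_i)`, linear for
#' `beta = 0` and saturating at `d / beta` for large amounts.
#'
#' @param x_i drug amount (ug).
#' @param d rate constant (1/day).
#' @param beta saturation constant (1/ug).
#' @return loss in ug/day.
#' @export
degradation_rate <- function(x_i, d, beta = 0) {
  if (any(x_i < 0) || any(d < 0) || any(beta < 0))
    stop("degradation_rate: inputs must be non-negative")
  d * x_i / (1 + beta * x_i)
}

#' PK right-hand side
#'
#' Time derivative of the compartment amounts: for each compartment, inflows
#' minus outflows over enabled transitions minus degradation. The plasma to
#' target-tissue coupling via `s` is read-only - no drug mass leaves the
#' system through it.
#'
#' @param x numeric vector of compartment amounts (ug).
#' @param topology a [pk_topology()].
#' @param params a [pk_params()] for that topology.
#' @return list with `dx` (derivatives, ug/day) and `degraded` (total
#'   instantaneous degradation rate, ug/day).
#' @export
pk_rhs <- function(x, topology, params) {
  n <- topology$n_compartments
  if (length(x) != n)
    stop("state has ", length(x), " amounts but topology has ", n,
         " compartments")
  if (length(params$w) != nrow(topology$transitions))
    stop("params do not match topology: need one w per enabled transition")
  dx <- numeric(n)
  tr <- topology$transitions
  J <- transition_rate(pmax(x[tr$from], 0), params$w, params$alpha)
  for (e in seq_len(nrow(tr))) {
    dx[tr$from[e]] <- dx[tr$from[e]] - J[e]
    dx[tr$to[e]] <- dx[tr$to[e]] + J[e]
  }
  D <- degradation_rate(pmax(x[topology$degradations], 0), params$d, params$beta)
  dx[topology$degradations] <- dx[topology$degradations] - D
  list(dx = dx, degraded = sum(D))
}

#' Plasma concentration from a PK state
#'
#' @param x0 plasma drug amount (ug), or a full state vector whose first
#'   element is plasma.
#' @param params a [pk_params()] (uses `V_plasma`).
#' @return concentration in ug/ml.
#' @export
plasma_concentration <- function(x0, params) {
  if (params$V_plasma <= 0) stop("V_plasma must be positive")
  x0[[1]] / params$V_plasma
}

#' Target-tissue concentration from plasma concentration
#'
#' Tissue drug levels are taken as a fraction of systemic levels at any
#' moment: `x_T = plasma_conc / s` with `s` in the realistic range 1-100, so
#' tissue concentration never exceeds plasma concentration.
#'
#' @param plasma_conc plasma concentration (ug/ml).
#' @param s plasma:tissue correlation factor.
#' @return tissue concentration (ug/ml).
#' @export
tissue_concentration <- function(plasma_conc, s) {
  if (s < 1) warning("s < 1 is outside the realistic range [1, 100]")
  plasma_conc / s
}

# Pack topology + params into the argument list the C++ integrator expects
# (0-based compartment indices).
pk_cpp_args <- function(topology, params) {
  list(n_pk = topology$n_compartments,
       edge_from = as.integer(topology$transitions$from - 1L),
       edge_to = as.integer(topology$transitions$to - 1L),
       w = params$w, alpha = params$alpha,
       deg_comp = as.integer(topology$degradations - 1L),
       d = params$d, beta = params$beta,
       V_plasma = params$V_plasma, s_factor = params$s,
       dose_comp = as.integer(topology$dose_compartment - 1L))
}
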