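#' Default PK model preset for a route
#'
#' Plausible-range murine IL-21 kinetics chosen for the package's default
#' ground truth (the published supplementary parameter tables are not
#' machine-readable; see the methods vignette for the rationale). Plasma
#' elimination is fast (half-life well under two hours), SC/IP absorption
#' runs over a few hours through the depot chain, and some degradation
#' processes are saturable (large beta), mirroring the qualitative findings
#' that IP transport is near-linear while SC transport and several
#' degradation steps are not.
#'
#' @param route `"IV"`, `"SC"` or `"IP"`.
#' @return list with elements `topology` and `params`.
#' @export
default_pk_model <- function(route = c("IV", "SC", "IP")) {
  route <- match.arg(route)
  topo <- pk_topology(route)
  if (route == "IV") {
    # edges: P->s1, s1->P, P->s2, s2->P, P->s3, s3->P
    w <- c(8, 6, 5, 4, 3, 2)
    alpha <- c(0, 0, 0.01, 0, 0, 0)
    # degradation: plasma, sec1..3
    d <- c(18, 4, 3, 2)
    beta <- c(0, 0.2, 0.5, 0)
    s <- 1  # unused for IV-only PK runs
  } else if (route == "SC") {
    # edges: depot->a1, a1->a2, a2->a3, a3->P, depot->P, P<->sec1..3
    w <- c(30, 34, 38, 42, 3, 2, 4, 1.5, 3, 1, 2)
    alpha <- c(0.05, 0.03, 0, 0, 0.08, 0, 0, 0, 0, 0, 0)
    d <- c(20, 5, 4, 3)
    beta <- c(0, 0.3, 0.5, 0)
    s <- 40
  } else {
    w <- c(40, 44, 48, 52, 6, 2, 4, 1.5, 3, 1, 2)
    alpha <- c(0.002, 0.001, 0, 0, 0.002, 0, 0, 0, 0, 0, 0)
    d <- c(20, 5, 4, 3)
    beta <- c(0, 0.3, 0.5, 0)
    s <- 12
  }
  list(topology = topo,
       params = pk_params(topo, w = w, alpha = alpha, d = d, beta = beta,
                          s = s, V_plasma = 2))
}

#' Default PD/disease parameter presets
#'
#' Named presets bundling the shared immune rate constants with
#' tumor-type-specific response intensity (`sigma`, `D_max`) and
#' (tumor type x therapy onset)-specific growth parameters (`r`, `K`).
#' B16 is treated as non-immunogenic and RenCa as moderately immunogenic.
#' The calibrated-style configuration is CTL-dominant (`k2 = 10 * k1`); pass
#' `equal_balance = TRUE` for the sensitivity configuration `k1 = k2`.
#'
#' @param preset one of `"B16-early"`, `"B16-late"`, `"RenCa-early"`,
#'   `"RenCa-late"`.
#' @param equal_balance use the equal effector balance configuration.
#' @return a [pd_params()].
#' @export
default_pd_params <- function(preset = c("B16-early", "B16-late",
                                         "RenCa-early", "RenCa-late"),
                              equal_balance = FALSE) {
  preset <- match.arg(preset)
  growth <- switch(preset,
    "B16-early"   = list(r = 0.60, K = 2.0e9),
    "B16-late"    = list(r = 0.55, K = 2.2e9),
    "RenCa-early" = list(r = 0.42, K = 1.8e9),
    "RenCa-late"  = list(r = 0.38, K = 2.0e9))
  immun <- if (grepl("^B16", preset)) {
    list(sigma = 3, D_max = 5e5)       # non-immunogenic
  } else {
    list(sigma = 4, D_max = 1e6)       # moderately immunogenic
  }
  k1 <- 5e-8
  k2 <- if (equal_balance) k1 else 10 * k1
  pd_params(sigma = immun$sigma, D_max = immun$D_max,
            k1 = k1, k2 = k2, r = growth$r, K = growth$K)
}

#' Full default ground-truth model
#'
#' The package's reference parameterization: PK models for all three routes,
#' route-specific plasma:tissue factors `s`, and the PD preset. This is the
#' ground truth from which the synthetic-data module generates virtual
#' cohorts, and the default preset on which the regimen scans run.
#'
#' @param preset PD preset name, see [default_pd_params()].
#' @param equal_balance see [default_pd_params()].
#' @return list with `pk` (named list of per-route PK models), `pd`
#'   ([pd_params()]), `preset` name, and `T0` (inoculum, cells).
#' @export
default_model <- function(preset = "B16-early", equal_balance = FALSE) {
  list(pk = list(IV = default_pk_model("IV"),
                 SC = default_pk_model("SC"),
                 IP = default_pk_model("IP")),
       pd = default_pd_params(preset, equal_balance = equal_balance),
       preset = preset,
       T0 = 1e5)
}
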