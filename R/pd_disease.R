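#' Pharmacodynamic and disease parameters
#'
#' Rate constants of the target-tissue immune/tumor system. IL-21 in the
#' tissue (concentration `u`, ug/ml) inhibits NK survival, drives a memory
#' factor that fuels CTL expansion toward a ceiling set by `sigma`/`D_max`,
#' and induces the per-cell cytotoxic-protein stores of both effectors; both
#' effectors kill tumor cells by mass action, and the tumor otherwise grows
#' logistically.
#'
#' Immune rate constants are shared across tumor types; `sigma` and `D_max`
#' are tumor-type-specific (immunogenicity), and `r`, `K` are specific to
#' tumor type and therapy-onset dataset.
#'
#' @param a_N NK influx into the tissue (cells/day).
#' @param mu_N NK baseline death rate (1/day).
#' @param i_N maximal drug-induced addition to the NK death rate (1/day).
#' @param K_N half-saturation of that effect (ug/ml).
#' @param q_M maximal memory accumulation rate (units/day).
#' @param K_M half-saturation of memory accumulation (ug/ml).
#' @param mu_M memory decay rate (1/day).
#' @param sigma CTL response-intensity (expansion per memory unit per day).
#' @param D_max maximal CTL number (cells).
#' @param mu_C CTL death rate (1/day).
#' @param h_N,h_C maximal cytotoxic-protein production rates (units/day).
#' @param K_uN,K_uC half-saturation of protein induction (ug/ml).
#' @param mu_pN,mu_pC protein decay rates (1/day).
#' @param k1 NK-tumor interaction affinity (per cell per protein-unit per day).
#' @param k2 CTL-tumor interaction affinity (same units); the calibrated
#'   configuration is CTL-dominant, `k2 = 10 * k1`; `k1 = k2` is the
#'   "equal effector balance" configuration.
#' @param r tumor intrinsic growth rate (1/day).
#' @param K tumor carrying capacity (cells).
#' @return an object of class `pd_params`.
#' @export
pd_params <- function(a_N = 6e5, mu_N = 0.1, i_N = 2, K_N = 0.02,
                      q_M = 1.3, K_M = 0.002, mu_M = 0.08,
                      sigma = 3, D_max = 5e5, mu_C = 0.25,
                      h_N = 4, K_uN = 0.002, mu_pN = 4,
                      h_C = 4, K_uC = 0.002, mu_pC = 4,
                      k1 = 5e-8, k2 = 5e-7,
                      r = 0.6, K = 2e9) {
  p <- list(a_N = a_N, mu_N = mu_N, i_N = i_N, K_N = K_N,
            q_M = q_M, K_M = K_M, mu_M = mu_M,
            sigma = sigma, D_max = D_max, mu_C = mu_C,
            h_N = h_N, K_uN = K_uN, mu_pN = mu_pN,
            h_C = h_C, K_uC = K_uC, mu_pC = mu_pC,
            k1 = k1, k2 = k2, r = r, K = K)
  if (any(unlist(p) < 0)) stop("all PD parameters must be >= 0")
  if (r <= 0 || K <= 0) stop("tumor growth requires r > 0 and K > 0")
  structure(p, class = "pd_params")
}

# fixed parameter order used by the C++ integrator
pd_param_vector <- function(p) {
  as.numeric(c(p$a_N, p$mu_N, p$i_N, p$K_N, p$q_M, p$K_M, p$mu_M,
               p$sigma, p$D_max, p$mu_C,
               p$h_N, p$K_uN, p$mu_pN, p$h_C, p$K_uC, p$mu_pC,
               p$k1, p$k2, p$r, p$K))
}

#' Logistic tumor growth rate
#'
#' @param T_cells tumor cell count.
#' @param r intrinsic growth rate (1/day).
#' @param K carrying capacity (cells).
#' @return growth rate in cells/day, `r * T * (1 - T/K)`.
#' @export
logistic_growth <- function(T_cells, r, K) {
  if (K <= 0) stop("carrying capacity K must be positive")
  if (any(T_cells < 0) || r < 0) stop("T and r must be non-negative")
  r * T_cells * (1 - T_cells / K)
}

#' Effector-mediated tumor kill rate
#'
#' Additive mass-action killing by NK cells and CTLs, each weighted by its
#' per-cell cytotoxic-protein load: `(k1*N*pN + k2*C*pC) * T`. Setting
#' `k2 = 0` removes all CTL killing (a T-cell-neutralized arm); `k1 = 0`
#' removes all NK killing (an NK-neutralized arm).
#'
#' @param T_cells,N,C tumor, NK, CTL counts.
#' @param pN,pC per-cell cytotoxic-protein levels.
#' @param k1,k2 interaction affinities.
#' @return loss in cells/day.
#' @export
tumor_kill_rate <- function(T_cells, N, C, pN, pC, k1, k2) {
  if (k1 < 0 || k2 < 0) stop("affinities must be non-negative")
  if (any(c(T_cells, N, C, pN, pC) < 0)) stop("states must be non-negative")
  (k1 * N * pN + k2 * C * pC) * T_cells
}

#' PD/disease right-hand side
#'
#' Time derivatives of the six tissue states given the current tissue IL-21
#' concentration `u`. Drug effects are Michaelis-type saturable terms. At
#' `u = 0` with `Mem = 0`, the immune states admit a drug-free steady state
#' (NK at influx/death balance, proteins at zero, CTL at zero), at which the
#' tumor grows purely logistically.
#'
#' @param state numeric vector or list with components `N`, `C`, `pN`, `pC`,
#'   `Mem`, `T` (in that order if unnamed).
#' @param u tissue IL-21 concentration (ug/ml).
#' @param params a [pd_params()].
#' @return named numeric vector of derivatives.
#' @export
pd_rhs <- function(state, u, params) {
  if (u < 0) stop("tissue concentration u must be non-negative")
  s <- as.numeric(unlist(state))
  names(s) <- c("N", "C", "pN", "pC", "Mem", "T")
  p <- params
  dN <- p$a_N - p$mu_N * s["N"] - p$i_N * u / (p$K_N + u) * s["N"]
  dC <- p$sigma * s["Mem"] * s["C"] * (1 - s["C"] / p$D_max) - p$mu_C * s["C"]
  dpN <- p$h_N * u / (p$K_uN + u) - p$mu_pN * s["pN"]
  dpC <- p$h_C * u / (p$K_uC + u) - p$mu_pC * s["pC"]
  dM <- p$q_M * u / (p$K_M + u) - p$mu_M * s["Mem"]
  dT <- logistic_growth(s[["T"]], p$r, p$K) -
    tumor_kill_rate(s[["T"]], s[["N"]], s[["C"]], s[["pN"]], s[["pC"]],
                    p$k1, p$k2)
  c(N = unname(dN), C = unname(dC), pN = unname(dpN), pC = unname(dpC),
    Mem = unname(dM), T = unname(dT))
}

#' Drug-free baseline PD state
#'
#' Initial conditions used throughout: NK and protein levels at their
#' drug-free steady state (`N = a_N/mu_N`, proteins 0), no memory, a small
#' CTL seed (10 cells) so expansion is possible once memory accumulates, and
#' the inoculum of 1e5 tumor cells at day 0.
#'
#' @param params a [pd_params()].
#' @param T0 initial tumor cell count (default 1e5 cells).
#' @param C_seed initial CTL seed (default 10 cells).
#' @return named numeric vector `(N, C, pN, pC, Mem, T)`.
#' @export
pd_baseline_state <- function(params, T0 = 1e5, C_seed = 10) {
  c(N = params$a_N / params$mu_N, C = C_seed, pN = 0, pC = 0, Mem = 0,
    T = T0)
}

#' Tumor cell count to volume
#'
#' Scales model tumor cell numbers to volume assuming 1e6 cells equal 1 mm3.
#'
#' @param T_cells tumor cell count.
#' @return tumor volume in mm3.
#' @export
cells_to_volume <- function(T_cells) {
  if (any(T_cells < 0)) stop("cell count must be non-negative")
  T_cells / 1e6
}

#' Analytic solution of the logistic tumor model
#'
#' Closed form for drug-free growth, used as an integration oracle.
#'
#' @param t time (days).
#' @param T0 initial cell count.
#' @param r growth rate (1/day).
#' @param K carrying capacity (cells).
#' @return cell count at `t`.
#' @export
logistic_analytic <- function(t, T0, r, K) {
  K * T0 * exp(r * t) / (K + T0 * (exp(r * t) - 1))
}
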