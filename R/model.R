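#' Adsorbed enzyme-site complex concentration at quasi-equilibrium
#'
#' Solves the mass-action adsorption equilibrium
#' \eqn{K_a (E_T - EN)(N_T - EN) = EN} with total site concentration
#' \eqn{N_T = \Gamma N_0}, returning the physical (smaller) root of the
#' binding quadratic:
#' \deqn{EN = \tfrac{1}{2}\left[\Gamma N_0 + E_T + 1/K_a -
#'   \sqrt{(E_T + \Gamma N_0 + 1/K_a)^2 - 4 E_T \Gamma N_0}\right].}
#' The root is evaluated through the larger-magnitude companion root and
#' the product of roots, which avoids catastrophic cancellation when
#' `K_a` is small or the two totals are far apart.
#'
#' @param params an [sc_params] object (only `K_a` and `Gamma` are used).
#' @param E_T total enzyme concentration, nM (vectorized, each >= 0).
#' @param N_0 substrate surface concentration, cm^2/L (> 0; scalar or
#'   vector recycled against `E_T`).
#' @return Adsorbed enzyme concentration `EN` in nM, same length as the
#'   recycled inputs; satisfies `0 <= EN <= min(E_T, Gamma*N_0)`.
#' @examples
#' wt <- petase_params("WT", "30C")
#' adsorbed_complex(wt, E_T = c(0, 50, 400), N_0 = 500)
#' @export
adsorbed_complex <- function(params, E_T, N_0) {
  stopifnot(inherits(params, "sc_params"))
  if (any(!is.finite(N_0)) || any(N_0 <= 0)) {
    stop("N_0 must be finite and strictly positive", call. = FALSE)
  }
  if (any(!is.finite(E_T)) || any(E_T < 0)) {
    stop("E_T must be finite and non-negative", call. = FALSE)
  }
  N_T <- params$Gamma * N_0              # nmol/cm^2 * cm^2/L = nmol/L = nM
  b <- E_T + N_T + 1 / params$K_a        # sum of the two quadratic roots
  disc <- sqrt(pmax(b^2 - 4 * E_T * N_T, 0))
  root_hi <- (b + disc) / 2
  EN <- ifelse(root_hi > 0, (E_T * N_T) / root_hi, 0)  # product of roots = E_T*N_T
  # guard tiny negative round-off, then the physical box
  EN[EN < 0 & EN > -1e-12 * pmax(N_T, 1)] <- 0
  pmin(pmax(EN, 0), pmin(E_T, N_T))
}

#' Site coverage
#'
#' Fraction of substrate sites occupied by adsorbed enzyme,
#' \eqn{\theta = EN / (\Gamma N_0)}, clamped to `[0, 1]`.
#'
#' @param EN adsorbed enzyme, nM.
#' @inheritParams adsorbed_complex
#' @return Coverage in `[0, 1]`.
#' @export
site_coverage <- function(EN, params, N_0) {
  stopifnot(inherits(params, "sc_params"))
  N_T <- params$Gamma * N_0
  if (any(EN < 0) || any(EN > N_T * (1 + 1e-9))) {
    stop("EN outside [0, Gamma*N_0]: inconsistent adsorbed amount",
         call. = FALSE)
  }
  pmin(pmax(EN / N_T, 0), 1)
}

#' Partition adsorbed enzyme into uncrowded and crowded pools
#'
#' At the fast crowding/uncrowding equilibrium the adsorbed enzyme splits
#' as \eqn{EN_{uc} = EN (1-\theta) / (K_c \theta + 1 - \theta)} and
#' \eqn{EN_c = EN - EN_{uc}}, so the two pools conserve `EN` exactly.
#'
#' @param EN adsorbed enzyme, nM (>= 0).
#' @param theta site coverage in `[0, 1]`.
#' @param K_c crowding equilibrium constant (> 0).
#' @return A list with components `EN_uc` and `EN_c` (nM).
#' @export
partition_adsorbed <- function(EN, theta, K_c) {
  if (any(theta < 0) || any(theta > 1)) {
    stop("theta must lie in [0, 1]", call. = FALSE)
  }
  if (any(K_c <= 0)) stop("K_c must be positive", call. = FALSE)
  if (any(EN < 0)) stop("EN must be non-negative", call. = FALSE)
  denom <- K_c * theta + 1 - theta
  if (any(denom == 0)) {
    stop("degenerate partition denominator K_c*theta + 1 - theta = 0",
         call. = FALSE)
  }
  EN_uc <- EN * (1 - theta) / denom
  list(EN_uc = EN_uc, EN_c = EN - EN_uc)
}

#' Apparent catalytic constant per adsorbed enzyme
#'
#' Coverage-dependent average catalytic rate per adsorbed enzyme
#' (the productivity per bound molecule):
#' \deqn{k_{app}(\theta) = k_{cat,uc}\,
#'   \frac{1 - \theta + c K_c \theta}{K_c \theta + 1 - \theta},
#'   \quad c = k_{cat,c}/k_{cat,uc}.}
#' It interpolates from `k_cat_uc` at zero coverage down to `k_cat_c` at
#' full coverage; `K_c` sets how fast the decay occurs.
#'
#' @param theta site coverage in `[0, 1]` (vectorized).
#' @param params an [sc_params] object.
#' @return Apparent catalytic constant, mA260/min/nM.
#' @export
apparent_kcat <- function(theta, params) {
  stopifnot(inherits(params, "sc_params"))
  if (any(theta < 0) || any(theta > 1)) {
    stop("theta must lie in [0, 1]", call. = FALSE)
  }
  denom <- params$K_c * theta + 1 - theta
  params$k_cat_uc * (1 - theta + params$c_ratio * params$K_c * theta) / denom
}

#' Macroscopic degradation rate and the full surface state
#'
#' Forward evaluation of the surface-crowding model at given total enzyme
#' and substrate loadings: adsorption equilibrium, coverage, the
#' crowded/uncrowded partition, the apparent catalytic constant, and the
#' macroscopic product-formation rate
#' \eqn{dP/dt = k_{app} EN = k_{cat,uc} EN_{uc} + k_{cat,c} EN_c}.
#'
#' @inheritParams adsorbed_complex
#' @return A data frame (one row per condition) with columns `E_T`, `N_0`,
#'   `N_T`, `EN`, `theta`, `EN_uc`, `EN_c`, `k_app`, and `rate`
#'   (mA260/min).
#' @examples
#' wt <- petase_params("WT", "30C")
#' degradation_rate(wt, E_T = seq(10, 600, by = 10), N_0 = 500)
#' @export
degradation_rate <- function(params, E_T, N_0) {
  stopifnot(inherits(params, "sc_params"))
  n <- max(length(E_T), length(N_0))
  E_T <- rep_len(E_T, n)
  N_0 <- rep_len(N_0, n)
  EN <- adsorbed_complex(params, E_T, N_0)
  theta <- site_coverage(EN, params, N_0)
  pools <- partition_adsorbed(EN, theta, params$K_c)
  k_app <- apparent_kcat(theta, params)
  data.frame(
    E_T = E_T, N_0 = N_0, N_T = params$Gamma * N_0,
    EN = EN, theta = theta,
    EN_uc = pools$EN_uc, EN_c = pools$EN_c,
    k_app = k_app, rate = k_app * EN
  )
}

#' Crowding-free limiting rate law (Mukai form)
#'
#' The surface-crowding rate law collapses to the classical
#' adjacent-free-site depolymerase model when crowded enzymes are fully
#' inactive and the crowding equilibrium is neutral (`K_c = 1`,
#' `k_cat_c = 0`): \eqn{dP/dt = k_{cat,uc} EN (1 - \theta)}. Since a
#' strictly zero catalytic constant is outside the parameter domain, the
#' limit is evaluated analytically.
#'
#' @param k_cat_uc uncrowded catalytic constant, mA260/min/nM.
#' @param params an [sc_params] object supplying `K_a` and `Gamma`.
#' @inheritParams adsorbed_complex
#' @return Rate in mA260/min (vectorized over conditions).
#' @export
mukai_limit_rate <- function(k_cat_uc, params, E_T, N_0) {
  stopifnot(inherits(params, "sc_params"))
  EN <- adsorbed_complex(params, E_T, N_0)
  theta <- site_coverage(EN, params, N_0)
  k_cat_uc * EN * (1 - theta)
}

#' Inverse Michaelis-Menten rate
#'
#' Conventional rate law for enzyme-saturating heterogeneous catalysis:
#' \eqn{rate = k_{inv} \Gamma_{inv} N_0 \, E_T / (K_{inv} + E_T)}.
#' Monotone in enzyme loading, so it cannot produce the high-loading
#' inhibition that the crowding model captures.
#'
#' @param p an [inv_mm_params] object.
#' @param E_T total enzyme concentration, nM.
#' @param N_0 substrate surface concentration, cm^2/L.
#' @return Rate in mA260/min.
#' @export
inv_mm_rate <- function(p, E_T, N_0) {
  stopifnot(inherits(p, "inv_mm_params"))
  if (any(E_T < 0)) stop("E_T must be non-negative", call. = FALSE)
  p$k_inv * p$Gamma_inv * N_0 * E_T / (p$K_inv + E_T)
}
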