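#' Surface-crowding model parameters
#'
#' Constructor for the five constants of the surface-crowding (SC) rate law
#' for interfacial depolymerases. Units follow the package-wide convention:
#' enzyme concentrations in nM, substrate surface concentration in cm^2/L,
#' site density in nmol/cm^2, and rates in mA260/min. Note that
#' `Gamma * N_0` is then directly in nmol/L = nM, so no conversion factor
#' appears anywhere in the model.
#'
#' @param K_a adsorption equilibrium constant (ratio of adsorption to
#'   desorption rate constants), 1/nM.
#' @param Gamma areal density of substrate sites on the film surface,
#'   nmol/cm^2.
#' @param K_c crowding equilibrium constant (ratio of the crowding to
#'   uncrowding transition rate constants), dimensionless.
#' @param k_cat_uc catalytic rate constant of an uncrowded adsorbed enzyme,
#'   mA260/min/nM.
#' @param k_cat_c catalytic rate constant of a crowded adsorbed enzyme,
#'   mA260/min/nM. Must not exceed `k_cat_uc`: crowded configurations are
#'   by definition the slower ones.
#' @return An object of class `sc_params`: a named list of the five
#'   constants plus the derived ratio `c = k_cat_c / k_cat_uc` (never an
#'   independent parameter).
#' @examples
#' p <- sc_params(K_a = 0.0290, Gamma = 0.0291, K_c = 0.890,
#'                k_cat_uc = 0.445, k_cat_c = 0.0588)
#' p$c_ratio
#' @export
sc_params <- function(K_a, Gamma, K_c, k_cat_uc, k_cat_c) {
  vals <- c(K_a = K_a, Gamma = Gamma, K_c = K_c,
            k_cat_uc = k_cat_uc, k_cat_c = k_cat_c)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all SC parameters must be finite and strictly positive", call. = FALSE)
  }
  if (k_cat_c > k_cat_uc * (1 + 1e-12)) {
    stop("k_cat_c must not exceed k_cat_uc (crowded enzymes are slower)",
         call. = FALSE)
  }
  structure(
    list(K_a = K_a, Gamma = Gamma, K_c = K_c,
         k_cat_uc = k_cat_uc, k_cat_c = k_cat_c,
         c_ratio = k_cat_c / k_cat_uc),
    class = "sc_params"
  )
}

#' @export
print.sc_params <- function(x, ...) {
  cat("Surface-crowding model parameters\n")
  cat(sprintf("  K_a      = %.4g 1/nM\n", x$K_a))
  cat(sprintf("  Gamma    = %.4g nmol/cm^2\n", x$Gamma))
  cat(sprintf("  K_c      = %.4g\n", x$K_c))
  cat(sprintf("  k_cat_uc = %.4g mA260/min/nM\n", x$k_cat_uc))
  cat(sprintf("  k_cat_c  = %.4g mA260/min/nM  (c = %.3g)\n",
              x$k_cat_c, x$c_ratio))
  invisible(x)
}

#' Inverse Michaelis-Menten parameters
#'
#' Comparison rate law for heterogeneous biocatalysis in which substrate
#' sites are limiting: rate saturates hyperbolically in enzyme and is
#' linear in substrate surface area. It has no crowding term and therefore
#' no interior productivity maximum.
#'
#' @param k_inv rate constant, mA260/min/nM.
#' @param Gamma_inv site areal density, nmol/cm^2.
#' @param K_inv half-saturation total enzyme concentration, nM.
#' @return Object of class `inv_mm_params`.
#' @export
inv_mm_params <- function(k_inv, Gamma_inv, K_inv) {
  vals <- c(k_inv, Gamma_inv, K_inv)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inverse-MM parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(k_inv = k_inv, Gamma_inv = Gamma_inv, K_inv = K_inv),
            class = "inv_mm_params")
}

#' @export
print.inv_mm_params <- function(x, ...) {
  cat("Inverse Michaelis-Menten parameters\n")
  cat(sprintf("  k_inv     = %.4g mA260/min/nM\n", x$k_inv))
  cat(sprintf("  Gamma_inv = %.4g nmol/cm^2\n", x$Gamma_inv))
  cat(sprintf("  K_inv     = %.4g nM\n", x$K_inv))
  invisible(x)
}

# Published SC parameter sets for IsPETase variants. Rows: 30 C fits for
# WT, TS, TSP, TSPNP; 55 C fits for TS, TSP, TSPNP. Used as generating
# truths for synthetic studies and as evaluation points for sensitivity
# ranking.
.petase_table <- list(
  `30C` = list(
    WT    = c(K_a = 0.0290,  Gamma = 0.0291, K_c = 0.890, k_cat_uc = 0.445, k_cat_c = 0.0588),
    TS    = c(K_a = 0.00196, Gamma = 0.141,  K_c = 20.4,  k_cat_uc = 1.11,  k_cat_c = 0.00441),
    TSP   = c(K_a = 0.00579, Gamma = 0.0859, K_c = 6.71,  k_cat_uc = 0.932, k_cat_c = 0.0386),
    TSPNP = c(K_a = 0.00847, Gamma = 0.0701, K_c = 6.89,  k_cat_uc = 1.01,  k_cat_c = 0.0555)
  ),
  `55C` = list(
    TS    = c(K_a = 0.00793, Gamma = 0.214, K_c = 21.2, k_cat_uc = 3.77, k_cat_c = 0.489),
    TSP   = c(K_a = 0.00832, Gamma = 0.228, K_c = 22.8, k_cat_uc = 4.71, k_cat_c = 0.582),
    TSPNP = c(K_a = 0.00869, Gamma = 0.269, K_c = 22.5, k_cat_uc = 4.23, k_cat_c = 0.492)
  )
)

#' Reference SC parameter sets for IsPETase variants
#'
#' Returns the reported surface-crowding parameter estimates for
#' PET-hydrolase variants: wild-type IsPETase (`WT`), the thermostable
#' quintuple mutant (`TS`), and its evolved derivatives (`TSP`, `TSPNP`),
#' at 30 or 55 degrees C. These are convenient generating truths for
#' forward simulation and recovery studies.
#'
#' @param variant one of `"WT"`, `"TS"`, `"TSP"`, `"TSPNP"` (at 55 C only
#'   the TS-based variants exist).
#' @param temperature `"30C"` or `"55C"`.
#' @return An [sc_params] object.
#' @examples
#' petase_params("WT", "30C")
#' @export
petase_params <- function(variant = c("WT", "TS", "TSP", "TSPNP"),
                          temperature = c("30C", "55C")) {
  temperature <- match.arg(temperature)
  variant <- match.arg(variant)
  tab <- .petase_table[[temperature]]
  if (is.null(tab[[variant]])) {
    stop(sprintf("no %s parameter set at %s", variant, temperature),
         call. = FALSE)
  }
  v <- tab[[variant]]
  sc_params(v[["K_a"]], v[["Gamma"]], v[["K_c"]],
            v[["k_cat_uc"]], v[["k_cat_c"]])
}

#' Available reference variants
#'
#' @param temperature `"30C"` or `"55C"`.
#' @return Character vector of variant labels with reference parameters.
#' @export
petase_variants <- function(temperature = c("30C", "55C")) {
  temperature <- match.arg(temperature)
  names(.petase_table[[temperature]])
}

# internal: run code with a temporary RNG seed, restoring global state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
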