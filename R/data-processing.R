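#' Initial rate from a product-accumulation time series
#'
#' Ordinary least-squares slope of the signal over a fixed early-time
#' window (e.g. 30-210 min for 30 C reactions, 15-105 min at 55 C, where
#' product accumulation is linear). Offsets in the signal do not affect
#' the slope.
#'
#' @param time time points, min (strictly increasing).
#' @param signal absorbance signal, mA260.
#' @param window length-2 numeric `c(t_start, t_end)`; points with
#'   `t_start <= time <= t_end` enter the regression (at least 3).
#' @return List with `rate` (slope, mA260/min) and `se` (its standard
#'   error).
#' @export
initial_rate <- function(time, signal, window = c(30, 210)) {
  if (length(time) != length(signal)) {
    stop("time and signal lengths differ", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 3) {
    stop("fewer than 3 points inside the rate window", call. = FALSE)
  }
  fit <- stats::lm(signal[keep] ~ time[keep])
  # a perfect line (noiseless series) is a legitimate input here; silence
  # summary.lm's reliability warning for that case
  co <- suppressWarnings(summary(fit))$coefficients
  list(rate = unname(co[2, 1]), se = unname(co[2, 2]))
}

#' Adsorbed amount from solution depletion
#'
#' Amount of enzyme bound to the film inferred from the drop in free
#' solution concentration between a film-free control and the reaction
#' with film. Negative depletions (replicate noise) are floored at zero
#' with a warning rather than treated as errors.
#'
#' @param conc_no_film free enzyme concentration without film, nM.
#' @param conc_with_film free enzyme concentration with film, nM.
#' @param volume_L reaction volume, L.
#' @return Adsorbed amount in pmol.
#' @examples
#' adsorbed_amount(80, 72, 0.001)  # 8 pmol
#' @export
adsorbed_amount <- function(conc_no_film, conc_with_film, volume_L) {
  if (any(volume_L <= 0)) stop("volume must be positive", call. = FALSE)
  delta <- conc_no_film - conc_with_film          # nM = nmol/L
  if (any(delta < 0)) {
    warning("negative depletion floored at 0 (with-film exceeds control)",
            call. = FALSE)
    delta <- pmax(delta, 0)
  }
  delta * volume_L * 1000                         # nmol -> pmol
}

#' Calibration standard curve
#'
#' Piecewise-linear standard curve with hard range enforcement: queries
#' outside the standards are an error, never an extrapolation.
#'
#' @param x standard abscissa values, strictly increasing (e.g.
#'   concentration, nM).
#' @param y measured response at each standard (e.g. fluorescence).
#' @param name label used in range-violation messages.
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(x, y, name = "standard curve") {
  if (length(x) != length(y) || length(x) < 2) {
    stop("need >= 2 paired standards", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("standard x values must be strictly increasing", call. = FALSE)
  }
  structure(list(x = x, y = y, name = name), class = "calibration_curve")
}

#' Evaluate or invert a calibration curve
#'
#' `calibrate_forward` maps abscissa to response; `calibrate_inverse`
#' maps a measured response back to the abscissa (requires a strictly
#' monotone response).
#'
#' @param curve a [calibration_curve].
#' @param x,y query values.
#' @return Interpolated values.
#' @export
calibrate_forward <- function(curve, x) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(x < min(curve$x)) || any(x > max(curve$x))) {
    stop(sprintf("query outside the range of %s (x in [%g, %g])",
                 curve$name, min(curve$x), max(curve$x)), call. = FALSE)
  }
  stats::approx(curve$x, curve$y, xout = x)$y
}

#' @rdname calibrate_forward
#' @export
calibrate_inverse <- function(curve, y) {
  stopifnot(inherits(curve, "calibration_curve"))
  dy <- diff(curve$y)
  if (!(all(dy > 0) || all(dy < 0))) {
    stop(sprintf("%s is not strictly monotone; cannot invert", curve$name),
         call. = FALSE)
  }
  lo <- min(curve$y); hi <- max(curve$y)
  if (any(y < lo) || any(y > hi)) {
    stop(sprintf("query outside the range of %s (y in [%g, %g])",
                 curve$name, lo, hi), call. = FALSE)
  }
  stats::approx(curve$y, curve$x, xout = y)$y
}

#' Product-corrected enzyme concentration from intrinsic fluorescence
#'
#' Soluble degradation product (MHET) quenches intrinsic protein
#' fluorescence, biasing solution-depletion concentrations. The
#' correction estimates the MHET concentration from the bulk A260
#' signal, looks up the expected fluorescence loss on an MHET-loss
#' standard curve, adds that loss back onto the raw fluorescence, and
#' inverts the protein standard curve at the corrected value.
#'
#' @param F_raw measured fluorescence of the supernatant.
#' @param A260 bulk product absorbance, mA260.
#' @param mhet_loss_curve [calibration_curve] mapping MHET concentration
#'   to expected fluorescence loss.
#' @param a260_to_mhet slope converting A260 to MHET concentration
#'   (assay-specific; supplied by the user).
#' @param protein_curve [calibration_curve] mapping enzyme concentration
#'   (nM) to fluorescence.
#' @return Enzyme concentration, nM.
#' @export
mhet_corrected_concentration <- function(F_raw, A260, mhet_loss_curve,
                                         a260_to_mhet, protein_curve) {
  mhet <- a260_to_mhet * A260
  loss <- calibrate_forward(mhet_loss_curve, mhet)
  calibrate_inverse(protein_curve, F_raw + loss)
}
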