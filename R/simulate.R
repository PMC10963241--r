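#' Default measurement grids
#'
#' Enzyme and substrate loading grids emulating the standard
#' depolymerization assay design: enzyme titrations of 10-600 nM (30 C)
#' or 20-1500 nM (55 C) crossed with film loadings of 200-1900 cm^2/L
#' (the areas of 2x5 mm through 19x5 mm films, both faces, in 1 ml).
#'
#' @param temperature `"30C"` or `"55C"`.
#' @return List with `E_T` (nM) and `N_0` (cm^2/L) vectors.
#' @export
default_grids <- function(temperature = c("30C", "55C")) {
  temperature <- match.arg(temperature)
  list(
    E_T = switch(temperature,
      `30C` = c(10, 25, 50, 100, 150, 200, 300, 400, 500, 600),
      `55C` = c(20, 50, 100, 200, 400, 600, 800, 1000, 1250, 1500)),
    N_0 = c(200, 500, 1000, 1500, 1900)
  )
}

#' Simulation configuration for synthetic kinetic datasets
#'
#' Bundles generating parameters, the measurement grid, the replicate
#' count and the noise model. Replicate rates are drawn as
#' `Normal(mean = model rate, sd = max(cv * mean, floor))` truncated at
#' zero, with `floor = floor_frac * max model rate over the grid` — the
#' absolute floor keeps weights finite at near-zero rates. The defaults
#' (5% CV, 3 replicates, 0.5% floor) reflect typical replicate scatter in
#' bulk-absorbance depolymerization assays.
#'
#' @param params generating [sc_params].
#' @param E_T,N_0 measurement grids (nM, cm^2/L).
#' @param n_replicates replicates per grid cell.
#' @param cv relative noise (SD / mean).
#' @param floor_frac absolute noise floor as a fraction of the maximum
#'   model rate over the grid.
#' @param temperature label carried through to the dataset.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(params, E_T = default_grids("30C")$E_T,
                       N_0 = default_grids("30C")$N_0,
                       n_replicates = 3, cv = 0.05, floor_frac = 0.005,
                       temperature = "30C") {
  stopifnot(inherits(params, "sc_params"))
  if (cv < 0 || floor_frac < 0) stop("noise levels must be >= 0",
                                     call. = FALSE)
  if (length(E_T) == 0 || length(N_0) == 0) {
    stop("grids must be nonempty", call. = FALSE)
  }
  structure(list(params = params, E_T = E_T, N_0 = N_0,
                 n_replicates = n_replicates, cv = cv,
                 floor_frac = floor_frac, temperature = temperature),
            class = "sim_config")
}

#' Generate a synthetic kinetic rate table
#'
#' Forward-evaluates the surface-crowding rate law over the configured
#' grid and adds truncated-Gaussian replicate noise, reporting per-cell
#' means and SDs exactly as a measured initial-rate table would.
#' Deterministic for a given seed.
#'
#' @param cfg a [sim_config].
#' @param seed integer seed.
#' @return Data frame with columns `E_T`, `N_0`, `rate_mean`, `rate_sd`,
#'   `n`, `rate_true`, plus a `temperature` attribute.
#' @export
generate_kinetics <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- expand.grid(E_T = cfg$E_T, N_0 = cfg$N_0)
  truth <- degradation_rate(cfg$params, grid$E_T, grid$N_0)$rate
  # the absolute floor is part of the *relative* noise model: at cv = 0 the
  # generator is exactly the model surface
  floor_sd <- if (cfg$cv > 0) cfg$floor_frac * max(truth) else 0
  out <- with_seed(seed, {
    reps <- vapply(seq_len(nrow(grid)), function(i) {
      sdev <- max(cfg$cv * truth[i], floor_sd)
      r <- stats::rnorm(cfg$n_replicates, truth[i], sdev)
      r <- pmax(r, 0)
      c(mean(r), stats::sd(r))
    }, numeric(2))
    data.frame(
      E_T = grid$E_T, N_0 = grid$N_0,
      rate_mean = reps[1, ],
      rate_sd = if (cfg$n_replicates > 1) reps[2, ] else 0,
      n = cfg$n_replicates,
      rate_true = truth
    )
  })
  if (cfg$cv == 0) {
    out$rate_mean <- truth
    out$rate_sd <- 0
  }
  attr(out, "temperature") <- cfg$temperature
  out
}

#' Generate a synthetic adsorption isotherm
#'
#' Forward-evaluates the adsorption equilibrium over an enzyme titration
#' at fixed film loading and adds replicate noise, emulating a
#' solution-depletion experiment. Observations are truncated to
#' `[0, E_T]`; the isotherm plateaus toward `Gamma * N_0`.
#'
#' @param params generating [sc_params] (`K_a`, `Gamma` used).
#' @param E_T enzyme titration, nM.
#' @param N_0 film loading of the adsorption assay, cm^2/L (default: a
#'   0.25-inch disc, both faces, in 1 ml).
#' @param n_replicates,cv,floor_frac noise model as in [sim_config()].
#' @param seed integer seed.
#' @return Data frame with columns `E_T`, `EN_obs`, `sd`, `n`, `EN_true`
#'   and an `N_0` attribute.
#' @export
generate_adsorption <- function(params, E_T = c(10, 25, 50, 100, 150, 200,
                                                300, 400, 500, 600),
                                N_0 = film_area("disc",
                                                diameter_cm = 2.54 / 4) / 0.001,
                                n_replicates = 3, cv = 0.05,
                                floor_frac = 0.005, seed = 1) {
  stopifnot(inherits(params, "sc_params"))
  truth <- adsorbed_complex(params, E_T, N_0)
  floor_sd <- if (cv > 0) floor_frac * max(truth) else 0
  out <- with_seed(seed, {
    reps <- vapply(seq_along(E_T), function(i) {
      sdev <- max(cv * truth[i], floor_sd)
      r <- stats::rnorm(n_replicates, truth[i], sdev)
      r <- pmin(pmax(r, 0), E_T[i])
      c(mean(r), stats::sd(r))
    }, numeric(2))
    data.frame(
      E_T = E_T,
      EN_obs = reps[1, ],
      sd = if (n_replicates > 1) reps[2, ] else 0,
      n = n_replicates,
      EN_true = truth
    )
  })
  if (cv == 0) {
    out$EN_obs <- truth
    out$sd <- 0
  }
  attr(out, "N_0") <- N_0
  out
}

#' Generate a linear early-time product time series
#'
#' Product signal accumulating at the model rate from an intercept, with
#' Gaussian noise, truncated at zero. Regressing the series over the
#' standard rate window recovers the generating rate within noise.
#'
#' @param params generating [sc_params].
#' @param E_T,N_0 reaction condition.
#' @param times sampling times, min (increasing).
#' @param intercept signal offset at time zero, mA260.
#' @param cv relative noise on the signal (of the final value).
#' @param seed integer seed.
#' @return Data frame with columns `time`, `signal` and attributes
#'   `rate_true`, `E_T`, `N_0`.
#' @export
generate_timeseries <- function(params, E_T, N_0,
                                times = seq(0, 240, by = 30),
                                intercept = 2, cv = 0.05, seed = 1) {
  if (any(diff(times) <= 0)) stop("times must be increasing", call. = FALSE)
  rate <- degradation_rate(params, E_T, N_0)$rate
  clean <- intercept + rate * times
  signal <- with_seed(seed, {
    pmax(clean + stats::rnorm(length(times), 0, cv * max(clean)), 0)
  })
  if (cv == 0) signal <- pmax(clean, 0)
  out <- data.frame(time = times, signal = signal)
  attr(out, "rate_true") <- rate
  attr(out, "E_T") <- E_T
  attr(out, "N_0") <- N_0
  out
}

#' Generate synthetic calibration curves
#'
#' A linear protein-fluorescence standard curve over 10-1000 nM and a
#' monotone (quadratic in concentration) MHET fluorescence-loss curve,
#' for exercising the product-corrected concentration workflow.
#'
#' @param protein_slope fluorescence units per nM.
#' @param protein_range concentration range of the protein standards, nM.
#' @param mhet_max maximum MHET concentration covered by the loss curve.
#' @param mhet_loss_scale loss at `mhet_max`.
#' @return List with `protein` and `mhet_loss` [calibration_curve]s.
#' @export
generate_calibration_curves <- function(protein_slope = 10,
                                        protein_range = c(10, 1000),
                                        mhet_max = 500,
                                        mhet_loss_scale = 200) {
  conc <- seq(protein_range[1], protein_range[2], length.out = 25)
  mhet <- seq(0, mhet_max, length.out = 25)
  list(
    protein = calibration_curve(conc, protein_slope * conc,
                                name = "protein fluorescence"),
    mhet_loss = calibration_curve(mhet,
                                  mhet_loss_scale * (mhet / mhet_max)^2,
                                  name = "MHET fluorescence loss")
  )
}

#' Generate point patterns at a prescribed density
#'
#' Thin wrapper around [simulate_point_pattern()] producing one or more
#' fields of view, for quadrant-analysis simulations.
#'
#' @param d density (`density_spec` or nm^-2).
#' @param window window geometry (see [point_pattern()]).
#' @param n_fields number of independent fields.
#' @param boundary boundary convention.
#' @param seed integer seed; field `i` uses `seed + i - 1`.
#' @return List of [point_pattern]s.
#' @export
generate_point_patterns <- function(d, window, n_fields = 2,
                                    boundary = c("bounded", "toroidal"),
                                    seed = 1) {
  boundary <- match.arg(boundary)
  lapply(seq_len(n_fields), function(i) {
    simulate_point_pattern(d, window, boundary = boundary, seed = seed + i - 1)
  })
}
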