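#' Read and write kinetic rate tables
#'
#' CSV dialect: columns `enzyme_nM`, `substrate_cm2_per_L`,
#' `rate_mA260_per_min`, `sd`, `n` (and optionally `variant`,
#' `temperature`). Internally the table uses the column names `E_T`,
#' `N_0`, `rate_mean`, `rate_sd`, `n`.
#'
#' @param path CSV file path.
#' @return `read_kinetics_csv`: a data frame in internal column naming.
#' @export
read_kinetics_csv <- function(path) {
  raw <- utils::read.csv(path)
  req <- c("enzyme_nM", "substrate_cm2_per_L", "rate_mA260_per_min")
  if (!all(req %in% names(raw))) {
    stop("kinetics CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    E_T = raw$enzyme_nM,
    N_0 = raw$substrate_cm2_per_L,
    rate_mean = raw$rate_mA260_per_min,
    rate_sd = if ("sd" %in% names(raw)) raw$sd else 0,
    n = if ("n" %in% names(raw)) raw$n else 1
  )
  if ("variant" %in% names(raw)) out$variant <- raw$variant
  out
}

#' @rdname read_kinetics_csv
#' @param kin internal-format kinetic data frame.
#' @export
write_kinetics_csv <- function(kin, path) {
  utils::write.csv(
    data.frame(
      enzyme_nM = kin$E_T,
      substrate_cm2_per_L = kin$N_0,
      rate_mA260_per_min = kin$rate_mean,
      sd = if ("rate_sd" %in% names(kin)) kin$rate_sd else 0,
      n = if ("n" %in% names(kin)) kin$n else 1
    ),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read and write adsorption isotherm tables
#'
#' CSV dialect: columns `enzyme_nM`, `adsorbed_nM`, `sd`, `n`.
#'
#' @param path CSV file path.
#' @return `read_adsorption_csv`: data frame with `E_T`, `EN_obs`, `sd`,
#'   `n`.
#' @export
read_adsorption_csv <- function(path) {
  raw <- utils::read.csv(path)
  req <- c("enzyme_nM", "adsorbed_nM")
  if (!all(req %in% names(raw))) {
    stop("adsorption CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    E_T = raw$enzyme_nM,
    EN_obs = raw$adsorbed_nM,
    sd = if ("sd" %in% names(raw)) raw$sd else 0,
    n = if ("n" %in% names(raw)) raw$n else 1
  )
}

#' @rdname read_adsorption_csv
#' @param ads internal-format adsorption data frame.
#' @export
write_adsorption_csv <- function(ads, path) {
  utils::write.csv(
    data.frame(
      enzyme_nM = ads$E_T,
      adsorbed_nM = ads$EN_obs,
      sd = if ("sd" %in% names(ads)) ads$sd else 0,
      n = if ("n" %in% names(ads)) ads$n else 1
    ),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a localization coordinate table
#'
#' CSV dialect: columns `fov_id`, `x`, `y`, and either a `units` column
#' or the `units` argument (`"nm"` or `"um"`); micron coordinates are
#' converted to nm on ingest.
#'
#' @param path CSV file path.
#' @param window disc window applied to every field (nm coordinates).
#' @param units fallback units when the file has no `units` column.
#' @return Named list of [point_pattern]s, one per `fov_id`.
#' @export
read_coordinates_csv <- function(path, window, units = c("nm", "um")) {
  units <- match.arg(units)
  raw <- utils::read.csv(path)
  req <- c("fov_id", "x", "y")
  if (!all(req %in% names(raw))) {
    stop("coordinates CSV must have columns fov_id, x, y", call. = FALSE)
  }
  u <- if ("units" %in% names(raw)) as.character(raw$units) else
    rep(units, nrow(raw))
  if (!all(u %in% c("nm", "um"))) {
    stop("units must be 'nm' or 'um'", call. = FALSE)
  }
  f <- ifelse(u == "um", 1000, 1)
  raw$x <- raw$x * f
  raw$y <- raw$y * f
  split_rows <- split(raw, raw$fov_id)
  lapply(split_rows, function(df) {
    point_pattern(df$x, df$y, window, boundary = "bounded")
  })
}

#' Write a fit result as a JSON report
#'
#' Flat machine-readable record of the estimates, intervals, objective,
#' BIC and per-start diagnostics of an `sc_fit`.
#'
#' @param fit an `sc_fit`.
#' @param path output JSON path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "sc_fit"))
  report <- list(
    fit_type = fit$fit_type,
    estimates = as.list(exp(fit$log_estimate)),
    ci95 = fit$ci95,
    objective = fit$objective,
    ssr = fit$ssr,
    n_obs = fit$n_obs,
    k_params = fit$k_params,
    bic = fit$bic,
    n_starts = fit$n_starts,
    converged_fraction = fit$converged_fraction,
    start_objectives = fit$start_objectives,
    flags = fit$flags
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
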