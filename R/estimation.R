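#' Variance-weighted sum of squared residuals
#'
#' The quadratic form \eqn{(y - \hat y)^\top V_\epsilon^{-1} (y - \hat y)}
#' with a diagonal measurement-uncertainty covariance. With unit variances
#' this is the ordinary SSR.
#'
#' @param observations numeric vector of measurements.
#' @param predictions model predictions, same length.
#' @param variances diagonal of the measurement covariance (strictly
#'   positive). Apply a variance floor upstream rather than passing zeros.
#' @return The scalar cost.
#' @export
weighted_ssr <- function(observations, predictions, variances) {
  if (length(observations) != length(predictions)) {
    stop("observations and predictions must have equal length", call. = FALSE)
  }
  variances <- rep_len(variances, length(observations))
  if (any(variances <= 0)) {
    stop("zero or negative variance entry; configure a variance floor ",
         "(see `variance_floor()`)", call. = FALSE)
  }
  sum((observations - predictions)^2 / variances)
}

#' Measurement variance with a relative floor
#'
#' Replicate variances of mean responses, floored at a fraction of the
#' largest observed response so that zero-variance replicates cannot blow
#' up the weighted objective. The floor default (1% of the maximum
#' observation, squared) keeps all weights finite without materially
#' down-weighting informative points.
#'
#' @param sd replicate standard deviations of each observation.
#' @param n_replicates replicates behind each mean (variance of the mean
#'   is `sd^2 / n`).
#' @param observations the observed means; only their maximum is used.
#' @param floor_frac floor expressed as a fraction of `max(observations)`.
#' @return Vector of variances, all positive.
#' @export
variance_floor <- function(sd, n_replicates, observations, floor_frac = 0.01) {
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  floor_var <- (floor_frac * max(abs(observations)))^2
  if (floor_var <= 0) floor_var <- .Machine$double.eps
  pmax(sd^2 / pmax(n_replicates, 1), floor_var)
}

#' Log-space prior for staged estimation
#'
#' Gaussian prior over a subset of the log parameters, carrying forward
#' the point estimates and covariance of an earlier fitting step.
#' Parameters fit for the first time in a later step are simply absent
#' from the prior and instill no cost.
#'
#' @param mu named vector of log-parameter means (names identify the
#'   active parameters).
#' @param V_mu covariance matrix of the log parameters in `mu`
#'   (symmetric positive definite).
#' @return Object of class `sc_prior` with the precision matrix cached.
#' @seealso [as_prior()] to build one directly from an adsorption fit.
#' @export
sc_prior <- function(mu, V_mu) {
  if (is.null(names(mu)) || any(!nzchar(names(mu)))) {
    stop("mu must be a fully named vector of log parameters", call. = FALSE)
  }
  V_mu <- as.matrix(V_mu)
  if (nrow(V_mu) != length(mu) || ncol(V_mu) != length(mu)) {
    stop("V_mu dimension does not match mu", call. = FALSE)
  }
  if (max(abs(V_mu - t(V_mu))) > 1e-8 * max(abs(V_mu), 1)) {
    stop("V_mu must be symmetric", call. = FALSE)
  }
  prec <- tryCatch(solve(V_mu), error = function(e) {
    stop("V_mu is not invertible on the active components", call. = FALSE)
  })
  structure(list(mu = mu, V_mu = V_mu, precision = prec,
                 active = names(mu)),
            class = "sc_prior")
}

#' Maximum-a-posteriori objective in log-parameter space
#'
#' Weighted SSR of the model predictions plus the prior quadratic penalty
#' \eqn{(\theta - \mu)^\top V_\mu^{-1} (\theta - \mu)} evaluated on the
#' prior's active components only (all in log space). With a `NULL` prior
#' this is the pure maximum-likelihood objective.
#'
#' @param log_params named vector of log parameters.
#' @param observations,variances measurement vector and its diagonal
#'   covariance (see [weighted_ssr()]).
#' @param model_fn function mapping the named log-parameter vector to the
#'   prediction vector.
#' @param prior an [sc_prior] or `NULL`.
#' @return Scalar cost.
#' @export
map_objective <- function(log_params, observations, variances, model_fn,
                          prior = NULL) {
  cost <- weighted_ssr(observations, model_fn(log_params), variances)
  if (!is.null(prior)) {
    stopifnot(inherits(prior, "sc_prior"))
    miss <- setdiff(prior$active, names(log_params))
    if (length(miss) > 0) {
      stop("log_params is missing prior components: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    d <- log_params[prior$active] - prior$mu
    cost <- cost + drop(t(d) %*% prior$precision %*% d)
  }
  cost
}

#' Multi-start bounded minimization
#'
#' Runs a quasi-Newton bounded minimizer (`optim`, `"L-BFGS-B"`) from
#' `n_starts` starting points sampled uniformly inside the box (log-space
#' boxes give log-uniform parameter sampling). Deterministic for a given
#' seed. Extra starting points can be supplied (e.g. warm starts); they
#' are appended after the sampled ones.
#'
#' @param objective function of the parameter vector to minimize.
#' @param lower,upper finite box bounds (named vectors).
#' @param n_starts number of random starts.
#' @param seed integer seed controlling the start sample.
#' @param extra_starts optional list of additional start vectors.
#' @param control passed to [stats::optim()].
#' @return List with `par` (best parameters), `value` (best objective),
#'   `starts` (per-start data frame: objective, convergence code),
#'   `converged_fraction` (share of starts ending within 1% of the best
#'   objective — a basin-of-attraction diagnostic), `n_starts`.
#' @export
multistart_optimize <- function(objective, lower, upper, n_starts = 64,
                                seed = 1, extra_starts = NULL,
                                control = list(maxit = 500)) {
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(upper <= lower)) {
    stop("bounds must be finite with upper > lower", call. = FALSE)
  }
  d <- length(lower)
  starts <- with_seed(seed, {
    m <- matrix(runif(n_starts * d), nrow = n_starts, ncol = d)
    sweep(sweep(m, 2, upper - lower, `*`), 2, lower, `+`)
  })
  start_list <- c(lapply(seq_len(n_starts), function(i) {
    v <- starts[i, ]; names(v) <- names(lower); v
  }), extra_starts)
  runs <- lapply(start_list, function(p0) {
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      stats::optim(p0, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = control),
      error = function(e) list(par = p0, value = Inf, convergence = 99L,
                               message = conditionMessage(e))
    )
    res
  })
  values <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(values))) {
    msgs <- unique(unlist(lapply(runs, function(r) r$message)))
    stop("all optimization starts failed: ",
         paste(utils::head(msgs, 3), collapse = "; "), call. = FALSE)
  }
  best <- which.min(values)
  tol <- max(abs(values[best]) * 0.01, 1e-8)
  structure(list(
    par = runs[[best]]$par,
    value = values[best],
    starts = data.frame(
      start = seq_along(runs),
      objective = values,
      convergence = vapply(runs, function(r) as.integer(r$convergence),
                           integer(1))
    ),
    converged_fraction = mean(values <= values[best] + tol),
    n_starts = length(runs)
  ), class = "multistart_result")
}

# internal: Gauss-Newton covariance of log parameters at the optimum.
# J[i, j] = d prediction_i / d log_param_j by central differences.
gauss_newton_cov <- function(model_fn, log_par, variances, h = 1e-5) {
  pred0 <- model_fn(log_par)
  J <- vapply(seq_along(log_par), function(j) {
    hi <- log_par; hi[j] <- hi[j] + h
    lo <- log_par; lo[j] <- lo[j] - h
    (model_fn(hi) - model_fn(lo)) / (2 * h)
  }, numeric(length(pred0)))
  W <- 1 / rep_len(variances, length(pred0))
  H <- crossprod(J * sqrt(W))
  cov <- tryCatch(solve(H), error = function(e) {
    # weakly identified directions: regularized pseudo-inverse, flagged wide
    s <- svd(H)
    keep <- s$d > max(s$d) * 1e-12
    s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
      t(s$u[, keep, drop = FALSE])
  })
  dimnames(cov) <- list(names(log_par), names(log_par))
  cov
}

# internal: assemble a fit-result object shared by all fitters
make_fit_result <- function(params, log_estimate, ms, ssr, n_obs, k_params,
                            cov_log, fit_type, refit = NULL,
                            fitted = NULL, flags = character()) {
  se <- sqrt(pmax(diag(cov_log), 0))
  ci95 <- data.frame(
    parameter = names(log_estimate),
    estimate = exp(log_estimate),
    lower = exp(log_estimate - 1.96 * se),
    upper = exp(log_estimate + 1.96 * se),
    row.names = NULL
  )
  structure(list(
    params = params,
    log_estimate = log_estimate,
    objective = ms$value,
    cov_log = cov_log,
    ssr = ssr,
    n_obs = n_obs,
    k_params = k_params,
    bic = bic(ssr, n_obs, k_params),
    n_starts = ms$n_starts,
    start_objectives = ms$starts,
    converged_fraction = ms$converged_fraction,
    ci95 = ci95,
    fit_type = fit_type,
    refit = refit,
    fitted = fitted,
    flags = flags
  ), class = "sc_fit")
}

#' @export
print.sc_fit <- function(x, ...) {
  cat(sprintf("Fit (%s): objective %.6g over %d starts (%.0f%% in best basin)\n",
              x$fit_type, x$objective, x$n_starts,
              100 * x$converged_fraction))
  print(x$ci95, digits = 4)
  cat(sprintf("weighted SSR %.6g on %d observations, BIC %.2f\n",
              x$ssr, x$n_obs, x$bic))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# default log-space sampling boxes; Gamma's upper edge may be tightened
# by the adsorption-capacity bound
.sc_bounds <- function() {
  list(
    lower = c(K_a = log(1e-5), Gamma = log(1e-4), K_c = log(1e-3),
              k_cat_uc = log(1e-3)),
    upper = c(K_a = log(1), Gamma = log(10), K_c = log(1e3),
              k_cat_uc = log(1e2))
  )
}

#' Step 1: fit adsorption parameters by maximum likelihood
#'
#' Fits the adsorption equilibrium constant `K_a` and the site areal
#' density `Gamma` to a solution-depletion isotherm (adsorbed enzyme vs
#' total enzyme at fixed substrate loading) by minimizing the weighted
#' SSR in the log space of the parameters, with multi-start bounded
#' optimization. The log-space Gauss-Newton covariance at the optimum is
#' returned so the result can seed the prior of the kinetic step.
#'
#' @param ads data frame with columns `E_T` (nM), `EN_obs` (nM), and
#'   optionally `sd` (nM) and `n` (replicates); at least 3 rows.
#' @param N_0 substrate surface concentration of the adsorption assay,
#'   cm^2/L.
#' @param n_starts,seed multi-start settings (see [multistart_optimize()]).
#' @param floor_frac relative variance floor (see [variance_floor()]).
#' @return An `sc_fit` with `params = list(K_a, Gamma)`. A `wide-K_a-CI`
#'   flag is raised when the data constrain only the plateau (all
#'   conditions saturating), leaving `K_a` weakly identified.
#' @export
fit_adsorption <- function(ads, N_0, n_starts = 32, seed = 1,
                           floor_frac = 0.01) {
  req <- c("E_T", "EN_obs")
  if (!all(req %in% names(ads))) {
    stop("ads must have columns E_T and EN_obs", call. = FALSE)
  }
  if (nrow(ads) < 3) stop("need at least 3 adsorption rows", call. = FALSE)
  if (any(ads$EN_obs < 0) || any(ads$EN_obs > ads$E_T * (1 + 1e-9))) {
    stop("EN_obs must lie in [0, E_T]", call. = FALSE)
  }
  sd <- if ("sd" %in% names(ads)) ads$sd else rep(0, nrow(ads))
  nrep <- if ("n" %in% names(ads)) ads$n else rep(1, nrow(ads))
  vars <- variance_floor(sd, nrep, ads$EN_obs, floor_frac)

  model_fn <- function(lp) {
    p <- sc_params(exp(lp[["K_a"]]), exp(lp[["Gamma"]]),
                   K_c = 1, k_cat_uc = 1, k_cat_c = 1)
    adsorbed_complex(p, ads$E_T, N_0)
  }
  obj <- function(lp) map_objective(lp, ads$EN_obs, vars, model_fn)
  b <- .sc_bounds()
  lower <- b$lower[c("K_a", "Gamma")]
  upper <- b$upper[c("K_a", "Gamma")]
  ms <- multistart_optimize(obj, lower, upper, n_starts = n_starts,
                            seed = seed)
  cov_log <- gauss_newton_cov(model_fn, ms$par, vars)
  flags <- character()
  if (sqrt(cov_log["K_a", "K_a"]) > 0.5) {
    flags <- c(flags, "wide-K_a-CI: adsorption data only weakly identify K_a")
  }
  refit <- function(obs_new, n_starts_boot = 4, seed_boot = 1) {
    obj_b <- function(lp) map_objective(lp, obs_new, vars, model_fn)
    multistart_optimize(obj_b, lower, upper, n_starts = n_starts_boot,
                        seed = seed_boot, extra_starts = list(ms$par))$par
  }
  make_fit_result(
    params = list(K_a = exp(ms$par[["K_a"]]), Gamma = exp(ms$par[["Gamma"]])),
    log_estimate = ms$par, ms = ms,
    ssr = weighted_ssr(ads$EN_obs, model_fn(ms$par), vars),
    n_obs = nrow(ads), k_params = 2, cov_log = cov_log,
    fit_type = "adsorption", refit = refit,
    fitted = model_fn(ms$par), flags = flags
  )
}

#' Build the kinetic-step prior from an adsorption fit
#'
#' Carries the step-1 point estimates and log-space covariance of
#' `(K_a, Gamma)` into an [sc_prior], and attaches the adsorption-capacity
#' upper bound for `Gamma` (the step-1 estimate inflated by twice its
#' relative standard error) used as a hard box constraint in the kinetic
#' fit.
#'
#' @param fit an adsorption `sc_fit`.
#' @return An [sc_prior] with attribute `gamma_cap`.
#' @export
as_prior <- function(fit) {
  stopifnot(inherits(fit, "sc_fit"), fit$fit_type == "adsorption")
  pr <- sc_prior(fit$log_estimate, fit$cov_log)
  se_logG <- sqrt(fit$cov_log["Gamma", "Gamma"])
  attr(pr, "gamma_cap") <- fit$params$Gamma * (1 + 2 * se_logG)
  pr
}

#' Step 2: fit all surface-crowding parameters by maximum a posteriori
#'
#' Fits the five SC parameters to a kinetic rate table by minimizing the
#' weighted SSR plus the log-space prior penalty carried over from the
#' adsorption step (which supplies `K_a` and `Gamma`; the remaining
#' parameters are fit for the first time and carry no prior cost).
#' The constraint `k_cat_c <= k_cat_uc` is enforced by optimizing the
#' ratio `c = k_cat_c / k_cat_uc` on a logit scale, and `Gamma` is
#' hard-bounded above by the adsorption capacity from the prior.
#'
#' @param kin data frame with columns `E_T` (nM), `N_0` (cm^2/L),
#'   `rate_mean` (mA260/min), and optionally `rate_sd`, `n`.
#' @param prior an [as_prior()] result; required, because the kinetic data
#'   alone confound adsorption and catalysis (use the two-step workflow).
#' @param n_starts,seed multi-start settings. The package default of 64
#'   starts locates the optimum reliably on grids of this size; a
#'   heavier exhaustive profile is available via `n_starts = 2000`.
#' @param floor_frac relative variance floor (see [variance_floor()]).
#' @return An `sc_fit` with `params` an [sc_params]; covariance and CIs
#'   are reported for the natural log parameters
#'   `(K_a, Gamma, K_c, k_cat_uc, k_cat_c)`. A `gamma-at-capacity` flag
#'   marks an optimum pinned at the adsorption-capacity bound.
#' @export
fit_kinetics <- function(kin, prior, n_starts = 64, seed = 1,
                         floor_frac = 0.01) {
  if (is.null(prior) || !inherits(prior, "sc_prior")) {
    stop("fit_kinetics requires the adsorption-step prior; run ",
         "fit_adsorption() then as_prior() first (two-step workflow)",
         call. = FALSE)
  }
  req <- c("E_T", "N_0", "rate_mean")
  if (!all(req %in% names(kin))) {
    stop("kin must have columns E_T, N_0, rate_mean", call. = FALSE)
  }
  if (length(unique(kin$E_T)) < 2) {
    stop("need at least 2 distinct E_T levels", call. = FALSE)
  }
  sd <- if ("rate_sd" %in% names(kin)) kin$rate_sd else rep(0, nrow(kin))
  nrep <- if ("n" %in% names(kin)) kin$n else rep(1, nrow(kin))
  vars <- variance_floor(sd, nrep, kin$rate_mean, floor_frac)

  gamma_cap <- attr(prior, "gamma_cap")
  b <- .sc_bounds()
  lower <- c(b$lower, qc = stats::qlogis(1e-6))
  upper <- c(b$upper, qc = stats::qlogis(1 - 1e-9))
  if (!is.null(gamma_cap)) {
    upper[["Gamma"]] <- min(upper[["Gamma"]], log(gamma_cap))
  }

  unpack <- function(p) {
    kuc <- exp(p[["k_cat_uc"]])
    sc_params(exp(p[["K_a"]]), exp(p[["Gamma"]]), exp(p[["K_c"]]),
              kuc, stats::plogis(p[["qc"]]) * kuc)
  }
  predict_fn <- function(p) {
    degradation_rate(unpack(p), kin$E_T, kin$N_0)$rate
  }
  obj <- function(p) map_objective(p, kin$rate_mean, vars, predict_fn, prior)
  ms <- multistart_optimize(obj, lower, upper, n_starts = n_starts,
                            seed = seed)
  est <- unpack(ms$par)

  # report covariance in natural log coordinates of the five parameters
  log_nat <- c(K_a = log(est$K_a), Gamma = log(est$Gamma), K_c = log(est$K_c),
               k_cat_uc = log(est$k_cat_uc), k_cat_c = log(est$k_cat_c))
  nat_model <- function(ln) {
    p <- sc_params(exp(ln[["K_a"]]), exp(ln[["Gamma"]]), exp(ln[["K_c"]]),
                   exp(ln[["k_cat_uc"]]),
                   min(exp(ln[["k_cat_c"]]), exp(ln[["k_cat_uc"]])))
    degradation_rate(p, kin$E_T, kin$N_0)$rate
  }
  cov_log <- gauss_newton_cov(nat_model, log_nat, vars)

  flags <- character()
  if (!is.null(gamma_cap) &&
      log(est$Gamma) > upper[["Gamma"]] - 1e-6) {
    flags <- c(flags, "gamma-at-capacity: Gamma pinned at adsorption bound")
  }
  refit <- function(obs_new, n_starts_boot = 4, seed_boot = 1) {
    obj_b <- function(p) map_objective(p, obs_new, vars, predict_fn, prior)
    pb <- multistart_optimize(obj_b, lower, upper, n_starts = n_starts_boot,
                              seed = seed_boot,
                              extra_starts = list(ms$par))$par
    e <- unpack(pb)
    c(K_a = log(e$K_a), Gamma = log(e$Gamma), K_c = log(e$K_c),
      k_cat_uc = log(e$k_cat_uc), k_cat_c = log(e$k_cat_c))
  }
  make_fit_result(
    params = est, log_estimate = log_nat, ms = ms,
    ssr = weighted_ssr(kin$rate_mean, predict_fn(ms$par), vars),
    n_obs = nrow(kin), k_params = 5, cov_log = cov_log,
    fit_type = "kinetics", refit = refit,
    fitted = predict_fn(ms$par), flags = flags
  )
}

#' Fit the inverse Michaelis-Menten comparison model
#'
#' Weighted least squares in log-parameter space for the three-parameter
#' enzyme-saturating rate law, on the same variance weighting as
#' [fit_kinetics()] so BIC values are directly comparable.
#'
#' @inheritParams fit_kinetics
#' @return An `sc_fit` with `params` an [inv_mm_params].
#' @export
fit_inv_mm <- function(kin, n_starts = 32, seed = 1, floor_frac = 0.01) {
  req <- c("E_T", "N_0", "rate_mean")
  if (!all(req %in% names(kin))) {
    stop("kin must have columns E_T, N_0, rate_mean", call. = FALSE)
  }
  sd <- if ("rate_sd" %in% names(kin)) kin$rate_sd else rep(0, nrow(kin))
  nrep <- if ("n" %in% names(kin)) kin$n else rep(1, nrow(kin))
  vars <- variance_floor(sd, nrep, kin$rate_mean, floor_frac)
  model_fn <- function(lp) {
    p <- inv_mm_params(exp(lp[["k_inv"]]), exp(lp[["Gamma_inv"]]),
                       exp(lp[["K_inv"]]))
    inv_mm_rate(p, kin$E_T, kin$N_0)
  }
  obj <- function(lp) map_objective(lp, kin$rate_mean, vars, model_fn)
  lower <- c(k_inv = log(1e-3), Gamma_inv = log(1e-4), K_inv = log(1e-1))
  upper <- c(k_inv = log(1e2), Gamma_inv = log(10), K_inv = log(1e5))
  ms <- multistart_optimize(obj, lower, upper, n_starts = n_starts,
                            seed = seed)
  cov_log <- gauss_newton_cov(model_fn, ms$par, vars)
  refit <- function(obs_new, n_starts_boot = 4, seed_boot = 1) {
    obj_b <- function(lp) map_objective(lp, obs_new, vars, model_fn)
    multistart_optimize(obj_b, lower, upper, n_starts = n_starts_boot,
                        seed = seed_boot, extra_starts = list(ms$par))$par
  }
  make_fit_result(
    params = inv_mm_params(exp(ms$par[["k_inv"]]), exp(ms$par[["Gamma_inv"]]),
                           exp(ms$par[["K_inv"]])),
    log_estimate = ms$par, ms = ms,
    ssr = weighted_ssr(kin$rate_mean, model_fn(ms$par), vars),
    n_obs = nrow(kin), k_params = 3, cov_log = cov_log,
    fit_type = "inv_mm", refit = refit,
    fitted = model_fn(ms$par)
  )
}

#' Bayesian information criterion (Gaussian-error convention)
#'
#' \eqn{BIC = n \ln(SSR/n) + k \ln n}. Lower is better; the difference
#' between two models fit to the same observations with the same
#' weighting measures whether extra parameters buy a real improvement.
#'
#' @param ssr (weighted) sum of squared residuals at the optimum (> 0).
#' @param n_obs number of observations (> `k_params`).
#' @param k_params number of fitted parameters.
#' @return The BIC value.
#' @export
bic <- function(ssr, n_obs, k_params) {
  if (ssr <= 0) stop("ssr must be positive", call. = FALSE)
  if (n_obs <= k_params) {
    stop("n_obs must exceed the number of parameters", call. = FALSE)
  }
  n_obs * log(ssr / n_obs) + k_params * log(n_obs)
}

#' Compare the SC and inverse-MM rate laws on one kinetic dataset
#'
#' Fits both models with shared variance weighting and reports their BIC
#' difference. Negative `delta_bic` (BIC of SC minus BIC of inverse MM)
#' favors the crowding model.
#'
#' @inheritParams fit_kinetics
#' @param n_starts_sc,n_starts_inv multi-start counts for the two fits.
#' @return List with `sc`, `inv_mm` (both `sc_fit`), and `delta_bic`.
#' @export
compare_models <- function(kin, prior, n_starts_sc = 64, n_starts_inv = 32,
                           seed = 1, floor_frac = 0.01) {
  fit_sc <- fit_kinetics(kin, prior, n_starts = n_starts_sc, seed = seed,
                         floor_frac = floor_frac)
  fit_inv <- fit_inv_mm(kin, n_starts = n_starts_inv, seed = seed,
                        floor_frac = floor_frac)
  list(sc = fit_sc, inv_mm = fit_inv,
       delta_bic = fit_sc$bic - fit_inv$bic)
}

#' Residual-bootstrap confidence intervals
#'
#' Percentile intervals in log-parameter space from refits to datasets
#' rebuilt as fitted values plus resampled residuals. Deterministic for a
#' given seed. Complements the Wald intervals reported by the fitters.
#'
#' @param fit an `sc_fit` from [fit_adsorption()], [fit_kinetics()] or
#'   [fit_inv_mm()].
#' @param observations the observation vector the fit was produced from
#'   (same order).
#' @param n_boot bootstrap replicates; fewer than 50 triggers a warning.
#' @param seed integer seed.
#' @param level interval coverage level.
#' @param n_starts_boot random starts per refit (each refit also warm
#'   starts from the original optimum).
#' @return Data frame with per-parameter `lower`, `upper` on the natural
#'   scale, plus the point estimate.
#' @export
bootstrap_ci <- function(fit, observations, n_boot = 200, seed = 1,
                         level = 0.95, n_starts_boot = 2) {
  stopifnot(inherits(fit, "sc_fit"))
  if (is.null(fit$refit)) stop("fit carries no refit closure", call. = FALSE)
  if (n_boot < 50) {
    warning("n_boot < 50: intervals will be unstable", call. = FALSE)
  }
  pred <- fit$fitted
  if (is.null(pred) || length(pred) != length(observations)) {
    stop("fit carries no fitted values matching the observations",
         call. = FALSE)
  }
  resid <- observations - pred
  draws <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      obs_b <- pred + sample(resid, length(resid), replace = TRUE)
      fit$refit(obs_b, n_starts_boot = n_starts_boot, seed_boot = b)
    }, numeric(length(fit$log_estimate))))
  })
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  data.frame(
    parameter = names(fit$log_estimate),
    estimate = exp(fit$log_estimate),
    lower = exp(qs[1, ]),
    upper = exp(qs[2, ]),
    row.names = NULL
  )
}
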