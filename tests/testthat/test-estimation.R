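test_that("weighted SSR matches hand arithmetic and the loop oracle", {
  expect_equal(weighted_ssr(c(1, 2), c(1, 2), c(1, 1)), 0)
  # residuals (1, 2) with variances (1, 4): 1/1 + 4/4 = 2
  expect_equal(weighted_ssr(c(1, 2), c(0, 0), c(1, 4)), 2)
  set.seed(21)
  obs <- rnorm(30); pred <- rnorm(30); vars <- runif(30, 0.5, 2)
  expect_equal(weighted_ssr(obs, pred, vars),
               oracle_weighted_ssr(obs, pred, vars))
  expect_error(weighted_ssr(1, 1, 0), "variance")
})

test_that("MAP objective adds the prior quadratic on active components only", {
  obs <- c(1, 2, 3)
  model_fn <- function(lp) exp(lp[["a"]]) * c(1, 2, 3)
  vars <- rep(1, 3)
  lp <- c(a = log(1), b = 0.7)

  # no prior: plain weighted SSR
  expect_equal(map_objective(lp, obs, vars, model_fn),
               weighted_ssr(obs, model_fn(lp), vars))

  # at mu with a perfect fit the cost is zero
  pr <- sc_prior(c(a = log(1)), matrix(0.25))
  expect_equal(map_objective(c(a = log(1), b = 99), obs, vars, model_fn, pr), 0)

  # random case: the two quadratic forms computed independently
  set.seed(4)
  mu <- c(a = rnorm(1), b = rnorm(1))
  V <- crossprod(matrix(rnorm(4), 2)) + diag(2) * 0.1
  dimnames(V) <- list(names(mu), names(mu))
  pr2 <- sc_prior(mu, V)
  lp2 <- c(a = rnorm(1), b = rnorm(1))
  d <- lp2 - mu
  expect_equal(map_objective(lp2, obs, vars, model_fn, pr2),
               weighted_ssr(obs, model_fn(lp2), vars) +
                 drop(t(d) %*% solve(V) %*% d))
})

test_that("multi-start optimizer solves convex and multimodal problems
           deterministically", {
  # convex quadratic: every start reaches the same optimum
  quad <- function(p) sum((p - c(0.3, -0.2))^2)
  r <- multistart_optimize(quad, c(-2, -2), c(2, 2), n_starts = 8, seed = 1)
  expect_equal(unname(r$par), c(0.3, -0.2), tolerance = 1e-5)
  expect_equal(r$converged_fraction, 1)

  # Rastrigin in 2D: global minimum 0 at the origin; a local optimizer
  # needs enough starts to hit the origin basin among the ~25 in the box
  rast <- function(p) 20 + sum(p^2 - 10 * cos(2 * pi * p))
  r2 <- multistart_optimize(rast, c(-2.56, -2.56), c(2.56, 2.56),
                            n_starts = 256, seed = 2)
  expect_equal(r2$value, 0, tolerance = 1e-6)
  expect_equal(unname(r2$par), c(0, 0), tolerance = 1e-4)

  # determinism: identical seed gives identical starts and best value
  r3 <- multistart_optimize(rast, c(-5.12, -5.12), c(5.12, 5.12),
                            n_starts = 16, seed = 7)
  r4 <- multistart_optimize(rast, c(-5.12, -5.12), c(5.12, 5.12),
                            n_starts = 16, seed = 7)
  expect_identical(r3$starts, r4$starts)
  expect_identical(r3$par, r4$par)
})

test_that("adsorption fit recovers generating parameters", {
  wt <- wt_params()

  # zero noise: recovery far inside 1e-4 relative
  ads0 <- generate_adsorption(wt, cv = 0, floor_frac = 0, seed = 1)
  f0 <- fit_adsorption(ads0, N_0 = attr(ads0, "N_0"), n_starts = 16, seed = 1)
  expect_lt(rel_err(f0$params$K_a, wt$K_a), 1e-4)
  expect_lt(rel_err(f0$params$Gamma, wt$Gamma), 1e-4)
  expect_true(all(f0$ci95$lower <= f0$ci95$estimate &
                    f0$ci95$estimate <= f0$ci95$upper))

  # 5% CV noise: estimates agree with a dense log-grid search oracle
  ads <- generate_adsorption(wt, cv = 0.05, seed = 8)
  vars <- variance_floor(ads$sd, ads$n, ads$EN_obs)
  f1 <- fit_adsorption(ads, N_0 = attr(ads, "N_0"), n_starts = 16, seed = 1)
  g <- oracle_adsorption_grid(ads, attr(ads, "N_0"), vars, n_grid = 200)
  # grid resolution is ~4% per step in each direction
  expect_lt(rel_err(f1$params$K_a, g$K_a), 0.05)
  expect_lt(rel_err(f1$params$Gamma, g$Gamma), 0.05)
  expect_lte(f1$objective, g$cost + 1e-9)
})

test_that("plateau-only adsorption data leave K_a weakly identified", {
  wt <- wt_params()
  # all conditions far above saturation of the ~18 nM site pool
  ads <- generate_adsorption(wt, E_T = c(2000, 3000, 4000, 5000, 6000),
                             cv = 0.02, seed = 3)
  f <- fit_adsorption(ads, N_0 = attr(ads, "N_0"), n_starts = 16, seed = 1)
  expect_lt(rel_err(f$params$Gamma, wt$Gamma), 0.1)
  ka_row <- f$ci95[f$ci95$parameter == "K_a", ]
  expect_gt(ka_row$upper / ka_row$lower, 10)  # wide interval
  expect_true(any(grepl("K_a", f$flags)))
})

test_that("kinetic fit requires the two-step prior and recovers noiseless
           parameters", {
  wt <- wt_params()
  kin0 <- generate_kinetics(sim_config(wt, cv = 0, floor_frac = 0), seed = 1)
  expect_error(fit_kinetics(kin0, prior = NULL), "two-step")

  ads0 <- generate_adsorption(wt, cv = 0, floor_frac = 0, seed = 1)
  pr <- as_prior(fit_adsorption(ads0, N_0 = attr(ads0, "N_0"),
                                n_starts = 16, seed = 1))
  fk <- fit_kinetics(kin0, pr, n_starts = 16, seed = 1)
  truth <- c(wt$K_a, wt$Gamma, wt$K_c, wt$k_cat_uc, wt$k_cat_c)
  expect_true(all(rel_err(unname(exp(fk$log_estimate)), truth) < 0.01))
  expect_lte(fk$params$k_cat_c, fk$params$k_cat_uc)
})

test_that("a prior centered on the unpenalized optimum does not move it", {
  wt <- wt_params()
  kin <- generate_kinetics(sim_config(wt, cv = 0.05), seed = 31)
  ads <- generate_adsorption(wt, cv = 0.05, seed = 32)
  f_ads <- fit_adsorption(ads, N_0 = attr(ads, "N_0"), n_starts = 16,
                          seed = 1)
  pr <- as_prior(f_ads)
  fk <- fit_kinetics(kin, pr, n_starts = 16, seed = 1)

  # re-center the prior exactly on the kinetic-step optimum
  pr2 <- sc_prior(fk$log_estimate[c("K_a", "Gamma")],
                  pr$V_mu)
  attr(pr2, "gamma_cap") <- attr(pr, "gamma_cap")
  fk2 <- fit_kinetics(kin, pr2, n_starts = 8, seed = 1)
  expect_equal(exp(fk2$log_estimate), exp(fk$log_estimate), tolerance = 0.02)
})

test_that("data generated without crowding yield a weak-crowding fit", {
  # inverse-MM truth: monotone saturating surface, no inhibition
  inv_true <- inv_mm_params(k_inv = 0.4, Gamma_inv = 0.05, K_inv = 80)
  grids <- default_grids("30C")
  grid <- expand.grid(E_T = grids$E_T, N_0 = grids$N_0)
  truth <- inv_mm_rate(inv_true, grid$E_T, grid$N_0)
  set.seed(44)
  kin <- data.frame(
    E_T = grid$E_T, N_0 = grid$N_0,
    rate_mean = pmax(truth * (1 + rnorm(nrow(grid), 0, 0.05)), 0),
    rate_sd = 0.05 * truth, n = 3
  )
  ads <- generate_adsorption(sc_params(1 / 80, 0.05, 1, 1, 1),
                             cv = 0.05, seed = 45)
  pr <- as_prior(fit_adsorption(ads, N_0 = attr(ads, "N_0"),
                                n_starts = 12, seed = 1))
  cmp <- compare_models(kin, pr, n_starts_sc = 12, n_starts_inv = 8, seed = 1)
  # SC must not claim strong crowding: either near-neutral catalytic ratio
  # or the BIC penalty not strongly favoring SC
  weak_crowding <- cmp$sc$params$c_ratio > 0.5 || cmp$delta_bic > -2 * log(nrow(kin))
  expect_true(weak_crowding)
})

test_that("BIC penalty arithmetic and model-selection direction", {
  # equal fit: fewer parameters win by exactly the penalty difference
  expect_equal(bic(10, 60, 5) - bic(10, 60, 3), 2 * log(60))
  # halved SSR buys more than 2 extra parameters at n = 60
  expect_equal(bic(5, 60, 5) - bic(10, 60, 3), 60 * log(0.5) + 2 * log(60))
  expect_lt(bic(5, 60, 5), bic(10, 60, 3))
  expect_error(bic(0, 10, 2), "positive")
  expect_error(bic(1, 3, 5), "exceed")
})

test_that("bootstrap intervals are deterministic and collapse at zero noise", {
  wt <- wt_params()
  ads0 <- generate_adsorption(wt, cv = 0, floor_frac = 0, seed = 1)
  f0 <- fit_adsorption(ads0, N_0 = attr(ads0, "N_0"), n_starts = 8, seed = 1)
  ci <- suppressWarnings(
    bootstrap_ci(f0, ads0$EN_obs, n_boot = 30, seed = 5, n_starts_boot = 0)
  )
  expect_lt(max(ci$upper / ci$lower), 1 + 1e-3)  # degenerate width

  ads <- generate_adsorption(wt, cv = 0.05, seed = 2)
  f1 <- fit_adsorption(ads, N_0 = attr(ads, "N_0"), n_starts = 8, seed = 1)
  ci1 <- bootstrap_ci(f1, ads$EN_obs, n_boot = 60, seed = 9,
                      n_starts_boot = 0)
  ci2 <- bootstrap_ci(f1, ads$EN_obs, n_boot = 60, seed = 9,
                      n_starts_boot = 0)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$lower < f1$ci95$estimate * 1.001))
  expect_true(all(ci1$upper > f1$ci95$estimate * 0.999))
  expect_warning(bootstrap_ci(f1, ads$EN_obs, n_boot = 20, seed = 1,
                              n_starts_boot = 0),
                 "unstable")
})
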