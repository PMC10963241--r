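test_that("adsorbed complex matches the bisection oracle and its limits", {
  wt <- wt_params()
  expect_equal(adsorbed_complex(wt, 0, 500), 0)

  # mass-action oracle at a representative condition
  EN <- adsorbed_complex(wt, 400, 500)
  expect_equal(EN, oracle_adsorbed(wt$K_a, wt$Gamma, 400, 500),
               tolerance = 1e-9)

  # saturation: huge affinity, enzyme excess -> EN -> N_T
  p_sat <- sc_params(1e6, 0.0291, 1, 1, 1)
  expect_equal(adsorbed_complex(p_sat, 1e5, 500), 0.0291 * 500,
               tolerance = 1e-6)

  # random-instance agreement with the oracle
  set.seed(7)
  for (i in 1:50) {
    K_a <- exp(runif(1, log(1e-4), log(1)))
    G <- exp(runif(1, log(1e-3), log(1)))
    E_T <- runif(1, 0.1, 2000)
    N_0 <- runif(1, 100, 2000)
    p <- sc_params(K_a, G, 1, 1, 1)
    expect_equal(adsorbed_complex(p, E_T, N_0),
                 oracle_adsorbed(K_a, G, E_T, N_0),
                 tolerance = 1e-8)
  }
})

test_that("binding quadratic is satisfied to 1e-9 over random draws", {
  set.seed(11)
  n <- 1e4
  K_a <- exp(runif(n, log(1e-4), log(1)))
  G <- exp(runif(n, log(1e-3), log(1)))
  E_T <- runif(n, 0.01, 2000)
  N_0 <- runif(n, 100, 2000)
  N_T <- G * N_0
  EN <- vapply(seq_len(n), function(i) {
    adsorbed_complex(sc_params(K_a[i], G[i], 1, 1, 1), E_T[i], N_0[i])
  }, numeric(1))
  resid <- K_a * (E_T - EN) * (N_T - EN) - EN
  expect_lt(max(abs(resid) / pmax(EN, 1e-10 * N_T)), 1e-9)
})

test_that("adsorbed complex is monotone in each driver", {
  base <- list(K_a = 0.01, G = 0.05, E_T = 100, N_0 = 500)
  en_at <- function(K_a = base$K_a, G = base$G, E_T = base$E_T,
                    N_0 = base$N_0) {
    adsorbed_complex(sc_params(K_a, G, 1, 1, 1), E_T, N_0)
  }
  set.seed(3)
  for (i in 1:200) {
    f <- exp(runif(1, log(0.2), log(5)))
    expect_gte(en_at(E_T = base$E_T * (1 + 1e-4) * f),
               en_at(E_T = base$E_T * f))
    expect_gte(en_at(K_a = base$K_a * (1 + 1e-4) * f),
               en_at(K_a = base$K_a * f))
    expect_gte(en_at(G = base$G * (1 + 1e-4) * f), en_at(G = base$G * f))
    expect_gte(en_at(N_0 = base$N_0 * (1 + 1e-4) * f),
               en_at(N_0 = base$N_0 * f))
  }
})

test_that("site coverage has its boundary values and oracle agreement", {
  wt <- wt_params()
  expect_equal(site_coverage(0, wt, 500), 0)
  expect_equal(site_coverage(wt$Gamma * 500, wt, 500), 1)
  EN <- adsorbed_complex(wt, 400, 500)
  expect_equal(site_coverage(EN, wt, 500),
               oracle_adsorbed(wt$K_a, wt$Gamma, 400, 500) / (wt$Gamma * 500),
               tolerance = 1e-9)
  expect_error(site_coverage(wt$Gamma * 500 * 1.01, wt, 500),
               "inconsistent")
})

test_that("adsorbed partition conserves EN, honors limits, matches the
           jump-process equilibrium", {
  expect_equal(partition_adsorbed(10, 0, 20.4),
               list(EN_uc = 10, EN_c = 0))
  expect_equal(partition_adsorbed(10, 1, 20.4),
               list(EN_uc = 0, EN_c = 10))

  # conservation is exact by construction over random inputs
  set.seed(5)
  EN <- runif(100, 0, 50)
  theta <- runif(100)
  K_c <- exp(runif(100, log(1e-3), log(1e3)))
  parts <- partition_adsorbed(EN, theta, K_c)
  expect_identical(parts$EN_uc + parts$EN_c, EN)

  # stochastic two-state equilibrium oracle at the standard example
  parts <- partition_adsorbed(10, 0.5, 20.4)
  frac_c_sim <- oracle_crowded_fraction(0.5, 20.4)
  expect_equal(parts$EN_c / 10, frac_c_sim, tolerance = 0.02)
})

test_that("apparent catalytic constant interpolates and decays monotonically", {
  wt <- wt_params()
  expect_equal(apparent_kcat(0, wt), wt$k_cat_uc)
  expect_equal(apparent_kcat(1, wt), wt$k_cat_c)

  # c = 1 collapses the ratio for all coverages
  p1 <- sc_params(0.01, 0.05, 5, 0.5, 0.5)
  theta <- seq(0, 1, by = 0.05)
  expect_equal(apparent_kcat(theta, p1), rep(0.5, length(theta)))

  # strict monotone decrease when c < 1, for random parameter draws
  set.seed(9)
  for (i in 1:50) {
    kuc <- exp(runif(1, log(0.01), log(10)))
    p <- sc_params(0.01, 0.05, exp(runif(1, log(0.01), log(100))),
                   kuc, kuc * runif(1, 0.01, 0.95))
    ks <- apparent_kcat(theta, p)
    expect_true(all(diff(ks) < 0))
    expect_true(all(ks <= p$k_cat_uc + 1e-12 & ks >= p$k_cat_c - 1e-12))
  }

  # agreement with the rate law evaluated and divided by EN
  st <- degradation_rate(wt, 400, 500)
  expect_equal(apparent_kcat(st$theta, wt), st$rate / st$EN,
               tolerance = 1e-12)
})

test_that("degradation rate satisfies its identities and inhibition shape", {
  wt <- wt_params()
  st0 <- degradation_rate(wt, 0, 500)
  expect_equal(st0$rate, 0)

  # rate = k_cat_uc*EN_uc + k_cat_c*EN_c = k_app*EN
  st <- degradation_rate(wt, seq(10, 600, by = 10), 500)
  expect_equal(st$rate, wt$k_cat_uc * st$EN_uc + wt$k_cat_c * st$EN_c,
               tolerance = 1e-12)
  expect_equal(st$rate, st$k_app * st$EN, tolerance = 1e-12)
  expect_equal(st$EN_uc + st$EN_c, st$EN, tolerance = 1e-15)

  # enzyme-excess limit: rate -> k_cat_c * Gamma * N_0
  st_inf <- degradation_rate(wt, 1e8, 500)
  expect_equal(st_inf$rate, wt$k_cat_c * wt$Gamma * 500, tolerance = 1e-3)

  # single interior maximum then decay toward the crowded plateau
  rates <- st$rate
  i_max <- which.max(rates)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(rates))
  expect_true(all(diff(rates[1:i_max]) > 0))
  expect_true(all(diff(rates[i_max:length(rates)]) < 0))
  expect_gt(min(rates[i_max:length(rates)]), wt$k_cat_c * wt$Gamma * 500)
})

test_that("crowding-free limit reduces to the adjacent-free-site rate law", {
  wt <- wt_params()
  set.seed(13)
  for (i in 1:20) {
    E_T <- runif(1, 1, 1000)
    N_0 <- runif(1, 100, 2000)
    # identity: evaluating the full model at K_c = 1 and c -> 0 equals
    # k_cat_uc * EN * (1 - theta)
    p_lim <- sc_params(wt$K_a, wt$Gamma, K_c = 1,
                       k_cat_uc = wt$k_cat_uc,
                       k_cat_c = wt$k_cat_uc * 1e-14)
    st <- degradation_rate(p_lim, E_T, N_0)
    expect_equal(st$rate, mukai_limit_rate(wt$k_cat_uc, wt, E_T, N_0),
                 tolerance = 1e-12)
  }
  # boundary behavior: full coverage halts the reaction
  p_tight <- sc_params(1e5, wt$Gamma, 1, wt$k_cat_uc, wt$k_cat_uc * 1e-14)
  EN <- adsorbed_complex(p_tight, 1e6, 500)
  theta <- site_coverage(EN, p_tight, 500)
  expect_gt(theta, 1 - 1e-4)
  expect_lt(mukai_limit_rate(wt$k_cat_uc, p_tight, 1e6, 500),
            wt$k_cat_uc * EN * 1e-3)
})

test_that("inverse MM rate saturates in enzyme without an interior maximum", {
  p <- inv_mm_params(k_inv = 0.4, Gamma_inv = 0.05, K_inv = 50)
  expect_equal(inv_mm_rate(p, 0, 500), 0)
  # plateau: E_T >> K_inv
  expect_equal(inv_mm_rate(p, 1e7, 500), 0.4 * 0.05 * 500,
               tolerance = 1e-4)
  rates <- inv_mm_rate(p, seq(1, 2000, by = 10), 500)
  expect_true(all(diff(rates) > 0))
})

test_that("parameter validation rejects unphysical values", {
  expect_error(sc_params(-1, 0.03, 1, 1, 1), "positive")
  expect_error(sc_params(0.03, 0.03, 1, 1, 2), "k_cat_c")
  expect_error(adsorbed_complex(wt_params(), -5, 500), "non-negative")
  expect_error(adsorbed_complex(wt_params(), 10, -500), "positive")
  expect_error(partition_adsorbed(10, 1.5, 1), "theta")
  expect_error(inv_mm_params(0, 1, 1), "positive")
})
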