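# Independent oracles used across the suite. These deliberately avoid the
# closed-form code paths they are checking.

# mass-action adsorption equilibrium solved by bisection on the free
# enzyme concentration E in [0, E_T]
oracle_adsorbed <- function(K_a, Gamma, E_T, N_0) {
  N_T <- Gamma * N_0
  if (E_T == 0) return(0)
  f <- function(E) K_a * E * (N_T - (E_T - E)) - (E_T - E)
  E_free <- stats::uniroot(f, c(0, E_T), tol = 1e-13)$root
  E_T - E_free
}

# long-run two-state jump process for the crowded/uncrowded partition:
# each adsorbed enzyme flips uncrowded -> crowded with propensity
# proportional to k_c * EN and back with propensity proportional to
# k_uc * (N_T - EN); the stationary crowded fraction is estimated from a
# long discrete-time chain
oracle_crowded_fraction <- function(theta, K_c, n_steps = 2e5, seed = 42) {
  # per-enzyme flip probabilities per step, scaled to keep both below 1/2
  p_c <- K_c * theta
  p_uc <- (1 - theta)
  scale <- 0.4 / max(p_c, p_uc)
  p_c <- p_c * scale
  p_uc <- p_uc * scale
  set.seed(seed)
  state <- 0L  # 0 = uncrowded, 1 = crowded
  crowded_time <- 0L
  u <- runif(n_steps)
  for (i in seq_len(n_steps)) {
    if (state == 0L) {
      if (u[i] < p_c) state <- 1L
    } else {
      if (u[i] < p_uc) state <- 0L
    }
    crowded_time <- crowded_time + state
  }
  crowded_time / n_steps
}

# elementwise loop version of the weighted SSR quadratic form
oracle_weighted_ssr <- function(obs, pred, vars) {
  total <- 0
  for (i in seq_along(obs)) total <- total + (obs[i] - pred[i])^2 / vars[i]
  total
}

# dense log-grid search for the two adsorption parameters
oracle_adsorption_grid <- function(ads, N_0, vars, n_grid = 200) {
  ka_grid <- exp(seq(log(1e-4), log(0.5), length.out = n_grid))
  g_grid <- exp(seq(log(1e-3), log(1), length.out = n_grid))
  best <- c(NA, NA, Inf)
  for (ka in ka_grid) {
    p <- sc_params(ka, 1, 1, 1, 1)
    for (g in g_grid) {
      pg <- sc_params(ka, g, 1, 1, 1)
      pred <- adsorbed_complex(pg, ads$E_T, N_0)
      cost <- sum((ads$EN_obs - pred)^2 / vars)
      if (cost < best[3]) best <- c(ka, g, cost)
    }
  }
  list(K_a = best[1], Gamma = best[2], cost = best[3])
}

# brute-force nearest-neighbor mean by explicit double loop
oracle_mean_nn <- function(x, y, toroidal = FALSE, W = NA, H = NA) {
  n <- length(x)
  mins <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- abs(x[i] - x[j]); dy <- abs(y[i] - y[j])
      if (toroidal) { dx <- min(dx, W - dx); dy <- min(dy, H - dy) }
      d <- dx^2 + dy^2
      if (d < best) best <- d
    }
    mins[i] <- sqrt(best)
  }
  mean(mins)
}

wt_params <- function() petase_params("WT", "30C")

# relative error helper
rel_err <- function(est, truth) abs(est - truth) / abs(truth)
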