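# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's own code paths (the grid kernel is
# C++; the oracles are plain R written from the definitions).

# L1-area agreement from its definition: 1 - int|ref((t-tau)/s) - det| / int det
oracle_agreement <- function(ref_t, ref_y, det_t, det_y, s, tau) {
  dt <- det_t[2L] - det_t[1L]
  u <- (det_t - tau) / s
  fit <- stats::approx(ref_t, ref_y, xout = u, yleft = 0, yright = 0)$y
  a <- 1 - sum(abs(fit - det_y)) * dt / (sum(det_y) * dt)
  min(max(a, 0), 1)
}

# Exhaustive dense grid search (the scale-recovery oracle)
oracle_dense_fit <- function(ref_t, ref_y, det_t, det_y,
                             s_values, tau_values) {
  best <- c(s = NA, tau = NA, a = -Inf)
  for (s in s_values) {
    for (tau in tau_values) {
      a <- oracle_agreement(ref_t, ref_y, det_t, det_y, s, tau)
      if (a > best["a"]) best <- c(s = s, tau = tau, a = a)
    }
  }
  best
}

# Spearman rho by explicit rank-then-Pearson arithmetic (no stats::cor)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# A normalized gamma-variate-like bump on a uniform grid, for matcher tests
test_bump <- function(hz = 10, duration = 240, t0 = 15, tp = 45, alpha = 2.5,
                      washout = 90, plateau = 0.35, dilate = 1) {
  tt <- seq(0, duration, by = 1 / hz)
  t0 <- t0 * dilate; tp <- tp * dilate; washout <- washout * dilate
  x <- (tt - t0) / (tp - t0)
  y <- numeric(length(tt))
  rise <- tt >= t0 & tt <= tp
  y[rise] <- x[rise]^alpha * exp(alpha * (1 - x[rise]))
  fall <- tt > tp
  y[fall] <- (1 - plateau) * exp(-(tt[fall] - tp) / washout) + plateau
  perfusion_curve(tt, y)
}

# Random kinetic parameters for seeded property tests
random_kinetics <- function(seed) {
  set.seed(seed)
  kinetic_params(
    onset_t0_s = stats::runif(1, 5, 25),
    peak_tp_s = stats::runif(1, 35, 70),
    alpha = stats::runif(1, 1.5, 4),
    washout_tau_s = stats::runif(1, 60, 120),
    plateau = stats::runif(1, 0.1, 0.5)
  )
}

# Small fast configs for unit tests (full defaults are exercised in
# test-acceptance.R)
fast_match_cfg <- function(...) {
  match_config(s_steps = 61L, tau_min_s = -20, tau_max_s = 20, ...)
}
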