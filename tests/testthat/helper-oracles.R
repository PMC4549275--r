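# Independent oracles and synthetic fixtures used across the suite.

# Posterior moments by brute-force 2-D Riemann quadrature of
# p(s|d) ~ N(d; s, Sigma_obs) * N(s; mu, Sigma). The grid is laid out
# along the prior's principal axes (mean +- half_width prior SDs per
# axis) so strongly correlated priors are resolved; the integrand itself
# is evaluated directly, never through the closed form under test.
quad_posterior_moments <- function(prior, noise, d, n_grid = 501,
                                   half_width = 8) {
  Sigma <- prior$Sigma
  eg <- eigen(Sigma, symmetric = TRUE)
  sds <- sqrt(eg$values)
  u1 <- seq(-half_width * sds[1], half_width * sds[1], length.out = n_grid)
  u2 <- seq(-half_width * sds[2], half_width * sds[2], length.out = n_grid)
  g <- expand.grid(u1 = u1, u2 = u2)
  # rotate principal coordinates back to (h, v)
  sh <- prior$mu[1] + eg$vectors[1, 1] * g$u1 + eg$vectors[1, 2] * g$u2
  sv <- prior$mu[2] + eg$vectors[2, 1] * g$u1 + eg$vectors[2, 2] * g$u2
  iS <- solve(Sigma)
  dh <- sh - prior$mu[1]; dv <- sv - prior$mu[2]
  log_prior <- -0.5 * (iS[1, 1] * dh^2 + 2 * iS[1, 2] * dh * dv + iS[2, 2] * dv^2)
  log_lik <- 0
  if (is.finite(noise$var_h)) log_lik <- log_lik - 0.5 * (d[1] - sh)^2 / noise$var_h
  if (is.finite(noise$var_v)) log_lik <- log_lik - 0.5 * (d[2] - sv)^2 / noise$var_v
  w <- exp(log_prior + log_lik - max(log_prior + log_lik))
  w <- w / sum(w)
  m <- c(sum(w * sh), sum(w * sv))
  ch <- sh - m[1]; cv <- sv - m[2]
  list(mean = m,
       cov = matrix(c(sum(w * ch^2), sum(w * ch * cv),
                      sum(w * ch * cv), sum(w * cv^2)), 2, 2))
}

# Synthetic trial records with known per-condition linear structure:
# dev[dim] = intercept + slope * s[dim] + N(0, resid_sd), shifts from the
# correlated test distribution. Used for slope-recovery checks.
make_linear_records <- function(slopes, intercept = 0, resid_sd = 0.3,
                                n_per_condition = 500, participant = "syn1",
                                rho = -0.999) {
  conds <- names(slopes)
  recs <- lapply(seq_along(conds), function(ci) {
    n <- n_per_condition
    z1 <- rnorm(n); z2 <- rnorm(n)
    s_h <- -1 + z1
    s_v <- 1 + rho * z1 + sqrt(1 - rho^2) * z2
    tibble::tibble(
      participant = participant, group = "synthetic", session = 1L,
      trial = ci * 10000L + seq_len(n), phase = "main",
      condition = conds[ci],
      s_h = s_h, s_v = s_v, d_h = s_h, d_v = s_v,
      dev_h = intercept + slopes[ci] * s_h + rnorm(n, 0, resid_sd),
      dev_v = intercept + slopes[ci] * s_v + rnorm(n, 0, resid_sd),
      hit = FALSE, prev_full_s_h = NA_real_, prev_full_s_v = NA_real_
    )
  })
  out <- dplyr::bind_rows(recs)
  out$hit <- hit_test(cbind(out$dev_h, out$dev_v))
  dplyr::arrange(out, trial)
}

# Records of a mean-compensating ideal actor in no-feedback trials:
# response = -mu (+ optional isotropic motor noise), deviation = s - mu.
make_ideal_none_records <- function(n = 600, motor_sd = 0,
                                    mu = c(-1, 1), rho = -0.999,
                                    participant = "ideal1") {
  z1 <- rnorm(n); z2 <- rnorm(n)
  s_h <- mu[1] + z1
  s_v <- mu[2] + rho * z1 + sqrt(1 - rho^2) * z2
  r_h <- -mu[1] + rnorm(n, 0, motor_sd)
  r_v <- -mu[2] + rnorm(n, 0, motor_sd)
  tibble::tibble(
    participant = participant, group = "synthetic", session = 1L,
    trial = seq_len(n), phase = "main", condition = "NONE",
    s_h = s_h, s_v = s_v, d_h = NA_real_, d_v = NA_real_,
    dev_h = s_h + r_h, dev_v = s_v + r_v,
    hit = hit_test(cbind(s_h + r_h, s_v + r_v)),
    prev_full_s_h = NA_real_, prev_full_s_v = NA_real_
  )
}

# small standard cohort used by several i/o and analysis tests
make_small_cohort <- function(seed = 42, n_participants = 2,
                              sessions = 2, trials = 250,
                              group = "correlated") {
  simulate_cohort(group_config(group), actor_config(), n_participants,
                  seed = seed, sessions = sessions, trials_per_session = trials)
}
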