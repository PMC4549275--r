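test_that("conjugate update moves the hyper-parameters as prescribed", {
  st <- niw_state()  # m0 = (0,0), kappa0 = 300, nu0 = 3000
  up <- niw_update_batch(st, matrix(rnorm(2000), 1000, 2))
  expect_equal(up$kappa, 1300)
  expect_equal(up$nu, 4000)
  one <- train_on_trial(st, c(2, 0))
  expect_equal(one$m, c(2 / 301, 0))
  expect_equal(one$trials_seen, 1L)
  # updating with the current location is a fixed point of the mean update
  same <- train_on_trial(st, st$m)
  expect_equal(same$m, st$m)
  expect_equal(same$kappa, st$kappa + 1)
  expect_equal(same$nu, st$nu + 1)
  expect_error(niw_update_batch(st, matrix(numeric(0), 0, 2)), "at least one")
  expect_error(niw_update_batch(st, c(1, NaN)), "finite")
})

test_that("sequential updates equal the batch update in any order", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:50, 1)
    data <- matrix(rnorm(2 * n, sd = 2), n, 2)
    st0 <- niw_state(m = rnorm(2), kappa = runif(1, 1, 500),
                     nu = runif(1, 3, 5000), S = diag(runif(2, 0.5, 10)))
    batch <- niw_update_batch(st0, data)
    seq1 <- Reduce(function(s, i) train_on_trial(s, data[i, ]), seq_len(n), st0)
    perm <- sample(n)
    seq2 <- Reduce(function(s, i) train_on_trial(s, data[i, ]), perm, st0)
    for (seqv in list(seq1, seq2)) {
      expect_equal(seqv$m, batch$m, tolerance = 1e-10)
      expect_equal(seqv$kappa, batch$kappa, tolerance = 1e-10)
      expect_equal(seqv$nu, batch$nu, tolerance = 1e-10)
      expect_equal(seqv$S, batch$S, tolerance = 1e-10)
    }
  }
})

test_that("likelihood peak is the bivariate Gaussian maximum density", {
  expect_equal(likelihood_max(obs_noise(1, 1)), 1 / (2 * pi))
  expect_equal(likelihood_max(obs_noise(0.2, 0.2)), 1 / (2 * pi * 0.2))
  expect_error(likelihood_max(obs_noise(0.2, Inf)), "finite")
  # acceptance ratio is a valid probability anywhere
  noise <- obs_noise(0.3, 7)
  lmax <- likelihood_max(noise)
  s <- matrix(rnorm(200, sd = 3), 100, 2)
  dens <- exp(-0.5 * ((0.2 - s[, 1])^2 / 0.3 + (-0.4 - s[, 2])^2 / 7)) /
    (2 * pi * sqrt(0.3 * 7))
  expect_true(all(dens / lmax <= 1 & dens / lmax > 0))
})

test_that("hyper-parameter sampling removes the noise and gates on PSD", {
  set.seed(21)
  st <- niw_state()
  full <- condition_noise("FULL")
  for (i in 1:200) {
    hs <- sample_hyperparameters(st, full)
    ev <- eigen(hs$Sigma0, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
  # the inverse-Wishart marginal has mean S / (nu - 3); with the study's
  # tight state the gate accepts essentially everything, so the empirical
  # mean of Theta = Sigma0 + Sigma_obs must match within 3 MC SE
  n <- 1e4
  draws <- vapply(seq_len(n), function(i) {
    sample_hyperparameters(st, full)$Sigma0[1, 1] + full$var_h
  }, numeric(1))
  iw_mean <- st$S[1, 1] / (st$nu - 3)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - iw_mean), 3 * se)
})

test_that("hand-rolled NIW draws agree with stats::rWishart moments", {
  set.seed(31)
  nu <- 50; S <- matrix(c(4, -1.5, -1.5, 2), 2, 2)
  n <- 2e4
  dr <- structbayes:::niw_draw_n(n, m = c(0, 0), kappa = 5, nu = nu, S = S)
  ref <- apply(stats::rWishart(n, nu, solve(S)), 3, function(w) {
    iw <- solve(w); c(iw[1, 1], iw[1, 2], iw[2, 2])
  })
  for (k in 1:3) {
    ours <- list(dr$t11, dr$t12, dr$t22)[[k]]
    se <- sqrt(var(ours) / n + var(ref[k, ]) / n)
    expect_lt(abs(mean(ours) - mean(ref[k, ])), 4 * se)
  }
  # psi | Theta has covariance E[Theta]/kappa around m
  expect_equal(var(dr$p1), mean(dr$t11) / 5, tolerance = 0.05)
})

test_that("an ill-posed state trips the PSD-gate cap", {
  st <- niw_state(kappa = 5, nu = 10, S = diag(0.1, 2))  # E[Theta] << Sigma_obs
  expect_error(sample_hyperparameters(st, condition_noise("FULL"),
                                      max_iter = 1000), "ill-posed")
})

test_that("responses negate the accepted shift and replay exactly", {
  st <- niw_state()
  set.seed(5); r1 <- respond(st, c(-1, 1), "FULL")
  expect_identical(r1$response, -r1$shift)
  expect_gte(r1$iterations, 1)
  set.seed(5); r2 <- respond(st, c(-1, 1), "FULL")
  expect_identical(r1, r2)
  # no-feedback with acceptance skipped draws straight from the belief
  set.seed(6)
  r3 <- respond(st, NULL, "NONE",
                actor_config(none_acceptance = "skip"))
  expect_identical(r3$response, -r3$shift)
  expect_error(respond(st, NULL, "FULL"), "required")
})

test_that("the rejection-loop cap errors or completes equivalently", {
  st <- niw_state()
  cfg_err <- actor_config(max_iter = 64, on_cap = "error")
  set.seed(8)
  expect_error(respond(st, c(40, 40), "FULL", cfg_err), "rejection loop")
  cfg_eq <- actor_config(max_iter = 64, on_cap = "equivalent")
  set.seed(8)
  r <- respond(st, c(8, -8), "FULL", cfg_eq)
  # the completed draw must follow the conjugate posterior of the belief
  b <- posterior_belief(shift_distribution(mu = st$m, sigma1 = sqrt(0.8),
                                           sigma2 = sqrt(0.8), rho = 0),
                        condition_noise("FULL"), c(8, -8))
  expect_lt(sqrt(sum((r$shift - b$mean)^2)), 6 * sqrt(max(diag(b$cov))))
})

test_that("accepted shifts follow the closed-form conjugate posterior", {
  set.seed(41)
  mu0 <- c(-0.8, 0.7)
  Sigma0 <- matrix(c(0.9, -0.5, -0.5, 0.8), 2, 2)
  noise <- condition_noise("FULL")
  d <- c(-0.4, 0.1)
  n <- 5000
  draws <- rejection_sample_shift(mu0, Sigma0, noise, d, n = n)
  b <- posterior_belief(shift_distribution(mu = mu0,
                                           sigma1 = sqrt(Sigma0[1, 1]),
                                           sigma2 = sqrt(Sigma0[2, 2]),
                                           rho = cov2cor(Sigma0)[1, 2]),
                        noise, d)
  se <- sqrt(diag(b$cov) / n)
  expect_lt(abs(mean(draws[, 1]) - b$mean[1]), 3 * se[1])
  expect_lt(abs(mean(draws[, 2]) - b$mean[2]), 3 * se[2])
  expect_equal(stats::cov(draws), b$cov, tolerance = 0.1)
  # two-sample agreement with direct posterior draws
  direct <- MASS::mvrnorm(n, b$mean, b$cov)
  expect_gt(stats::ks.test(draws[, 1], direct[, 1])$p.value, 0.01)
  expect_gt(stats::ks.test(draws[, 2], direct[, 2])$p.value, 0.01)
})

test_that("training on correlated shifts turns the believed covariance negative", {
  set.seed(51)
  full <- condition_noise("FULL")
  train <- function(rho) {
    st <- niw_state()
    s <- draw_shift(group_config(if (rho == 0) "uncorrelated" else "correlated"),
                    "FULL", n = 2000)
    niw_update_batch(st, s)
  }
  cor_state <- train(-0.999)
  unc_state <- train(0)
  sig_cor <- tidy(cor_state)
  sig_unc <- tidy(unc_state)
  expect_lt(sig_cor$cov_hv, 0)
  expect_lt(abs(sig_unc$rho), 0.1)
  expect_lt(sig_cor$rho, sig_unc$rho)
})

test_that("learner snapshots round-trip through JSON", {
  st <- niw_update_batch(niw_state(), matrix(rnorm(20), 10, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_niw_state(st, path, seed = 99L)
  back <- read_niw_state(path)
  expect_equal(back$m, st$m)
  expect_equal(back$S, st$S)
  expect_equal(back$kappa, st$kappa)
  expect_equal(back$trials_seen, st$trials_seen)
  expect_equal(attr(back, "seed"), 99L)
})
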