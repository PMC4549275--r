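test_that("robust fits recover exact lines and resist outliers", {
  x <- seq_len(20)
  f <- robust_line(x, 0.5 * x + 1)
  expect_equal(f$slope, 0.5, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  # noiseless data leaves every bisquare weight at one: identical to OLS
  ols <- coef(lm(I(0.5 * x + 1) ~ x))
  expect_equal(c(f$intercept, f$slope), unname(ols), tolerance = 1e-10)
  # constant response
  expect_equal(robust_line(x, rep(2, 20))$slope, 0)
  expect_error(robust_line(rep(1, 10), rnorm(10)), "constant")
  expect_error(robust_line(1:2, 1:2), "at least 3")
  # one gross outlier: robust fit beats OLS
  set.seed(1)
  x <- seq(0, 5, length.out = 50)
  y <- x + rnorm(50, 0, 0.1)
  y[25] <- y[25] + 10 * 0.1 * 10
  rob <- robust_line(x, y)$slope
  naive <- unname(coef(lm(y ~ x))[2])
  expect_lt(abs(rob - 1), abs(naive - 1))
  expect_lt(abs(rob - 1), 0.02)
})

test_that("tidiers expose fits in broom shape", {
  f <- robust_line(1:10, 2 * (1:10), dimension = "v", condition = "NONE")
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "slope"))
  expect_equal(td$estimate[2], 2, tolerance = 1e-8)
  gl <- glance(f)
  expect_equal(gl$n, 10)
  expect_equal(gl$condition, "NONE")
})

test_that("slope recovery is accurate across the full slope range", {
  set.seed(2)
  slopes <- c(FULL = 0, PARTIAL_H = 0.25, PARTIAL_V = 0.5, NONE = 0.75)
  recs <- make_linear_records(slopes, intercept = 0.4, resid_sd = 0.3,
                              n_per_condition = 500)
  for (dim in c("h", "v")) {
    got <- condition_slopes(recs, dim, by_participant = FALSE)
    expect_equal(got$slope[match(names(slopes), got$condition)],
                 unname(slopes), tolerance = 0.05)
  }
})

test_that("ideal no-feedback behaviour yields unit slope and -mu intercept", {
  set.seed(3)
  recs <- make_ideal_none_records(n = 500, motor_sd = 0.05)
  got_h <- condition_slopes(recs, "h", by_participant = FALSE)
  got_v <- condition_slopes(recs, "v", by_participant = FALSE)
  expect_equal(got_h$slope, 1, tolerance = 0.05)
  expect_equal(got_h$intercept, 1, tolerance = 0.05)   # -mu_h = +1
  expect_equal(got_v$slope, 1, tolerance = 0.05)
  expect_equal(got_v$intercept, -1, tolerance = 0.05)  # -mu_v = -1
})

test_that("sliding windows track piecewise structure and reject bad windows", {
  set.seed(4)
  # constant statistic -> constant series
  recs <- make_linear_records(c(NONE = 0.5), resid_sd = 0, n_per_condition = 300)
  ser <- sliding_series(recs, "slope", conditions = "NONE", window = 50,
                        dimension = "v")
  expect_true(all(abs(ser$value - 0.5) < 1e-8))
  # slope 1 then slope 0: the series falls, endpoints near the truth
  first <- make_linear_records(c(NONE = 1), resid_sd = 0.05, n_per_condition = 300)
  second <- make_linear_records(c(NONE = 0), resid_sd = 0.05, n_per_condition = 300)
  second$trial <- second$trial + max(first$trial)
  both <- dplyr::bind_rows(first, second)
  ser <- sliding_series(both, "slope", conditions = "NONE", window = 100,
                        dimension = "v")
  expect_lt(abs(ser$value[1] - 1), 0.05)
  expect_lt(abs(ser$value[nrow(ser)] - 0), 0.05)
  expect_error(sliding_series(recs, "slope", conditions = "NONE", window = 1000),
               "larger than")
})

test_that("windowing is invariant to record order", {
  set.seed(5)
  recs <- make_linear_records(c(NONE = 0.7), resid_sd = 0.2, n_per_condition = 200)
  shuffled <- recs[sample(nrow(recs)), ]
  a <- sliding_series(recs, "slope", conditions = "NONE", window = 60,
                      dimension = "v")
  b <- sliding_series(shuffled, "slope", conditions = "NONE", window = 60,
                      dimension = "v")
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("cohort medians truncate to the shortest support", {
  base <- tibble::tibble(center = 1:10, session = 1L, value = 0)
  mk <- function(v, n, p) {
    s <- base[seq_len(n), ]; s$value <- v; s$participant <- p; s
  }
  ser <- dplyr::bind_rows(mk(0, 10, "a"), mk(1, 10, "b"), mk(2, 10, "c"))
  med <- cohort_median_series(ser)
  expect_equal(med$value, rep(1, 10))
  # identical series stay themselves
  ser2 <- dplyr::bind_rows(mk(0.3, 8, "a"), mk(0.3, 8, "b"))
  expect_equal(cohort_median_series(ser2)$value, rep(0.3, 8))
  # unequal lengths truncate
  ser3 <- dplyr::bind_rows(mk(0, 10, "a"), mk(1, 6, "b"))
  expect_equal(nrow(cohort_median_series(ser3)), 6)
  expect_error(cohort_median_series(mk(1, 5, "a")), "at least 2")
})

test_that("pooled uninformative-dimension slope is free of between-type bias", {
  set.seed(6)
  # both partial types follow slope 0.6 in their uninformative dimension
  recs <- make_linear_records(c(PARTIAL_H = 0.6, PARTIAL_V = 0.6),
                              resid_sd = 0.2, n_per_condition = 250)
  ser <- sliding_series(recs, "slope", window = 100)
  expect_equal(median(ser$value), 0.6, tolerance = 0.05)
})

test_that("no-feedback endpoints separate sampling from mean compensation", {
  # exact ideal actor: constant endpoints, correlation undefined
  set.seed(7)
  exact <- make_ideal_none_records(n = 100, motor_sd = 0)
  ep <- nofeedback_endpoints(exact)
  expect_equal(c(ep$mean_h, ep$mean_v), c(1, -1))
  expect_true(is.na(ep$xy_corr))
  # isotropic motor noise does not induce endpoint correlation
  noisy <- make_ideal_none_records(n = 600, motor_sd = 0.5)
  ep2 <- nofeedback_endpoints(noisy)
  expect_lt(abs(ep2$xy_corr), 0.1)
  expect_true(ep2$corr_lo < ep2$xy_corr & ep2$xy_corr < ep2$corr_hi)
  expect_equal(ep2$mean_h, 1, tolerance = 0.1)
  expect_equal(ep2$mean_v, -1, tolerance = 0.1)
})

test_that("carryover correlations recover the generating weight", {
  g <- group_config("correlated")
  rec <- simulate_human_like(g, humanlike_config(motor_sd = 0.3, carryover = -0.3),
                             sessions = 1, trials_per_session = 600, seed = 8)
  ct <- carryover_correlation(rec, n_perm = 500, seed = 1)
  expect_true(all(ct$cor < 0))
  expect_true(all(ct$p_perm < 0.05))
  # shuffling the previous-shift column destroys the effect
  set.seed(9)
  shuf <- rec
  none_i <- which(shuf$condition == "NONE")
  shuf$prev_full_s_h[none_i] <- sample(shuf$prev_full_s_h[none_i])
  shuf$prev_full_s_v[none_i] <- sample(shuf$prev_full_s_v[none_i])
  ct2 <- carryover_correlation(shuf, n_perm = 500, seed = 1)
  expect_true(all(abs(ct2$cor) < abs(ct$cor)))
})

test_that("group comparisons use exact small-sample distributions", {
  # six same-sign values: exact binomial sign test
  res <- group_compare(c(-2, -1, -3, -0.5, -1.2, -0.8))
  expect_equal(res$p_value, 2 * (1 / 2)^6)
  # fully separated groups: exact rank-sum p = 2 / choose(12, 6)
  res2 <- group_compare(1:6, 7:12)
  expect_equal(res2$p_value, 2 / choose(12, 6))
  expect_true(res2$exact)
  # identical paired samples are degenerate
  res3 <- group_compare(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_true(is.na(res3$p_value))
  expect_match(res3$note, "degenerate")
  # paired comparison detects a one-sided shift
  set.seed(10)
  a <- rnorm(10); b <- a + 1
  res4 <- group_compare(a, b, paired = TRUE)
  expect_lt(res4$p_value, 0.01)
})

test_that("the full analysis bundle assembles on a small cohort", {
  rec <- make_small_cohort(seed = 11, n_participants = 2, sessions = 1,
                           trials = 400)
  an <- analyze_records(rec, slope_window = 40, corr_window = 30,
                        mean_window = 40, n_perm = 200)
  expect_s3_class(an, "sb_analysis")
  expect_true(all(c("participant", "condition", "slope") %in% names(an$slopes)))
  expect_false(is.null(an$partial_slope$median))
  expect_equal(nrow(an$carryover), 4)  # 2 participants x 2 dimensions
  expect_true(all(is.finite(an$endpoints$mean_h)))
})
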