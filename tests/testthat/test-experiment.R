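test_that("session schedules follow the study layout", {
  g <- group_config("correlated")
  set.seed(1)
  s1 <- schedule_session(g, 1)
  expect_equal(nrow(s1), 1000)
  expect_equal(sum(s1$phase == "training_stage_1"), 50)
  expect_equal(sum(s1$phase == "training_stage_2"), 50)
  expect_equal(sum(s1$phase == "training_stage_3"), 100)
  expect_true(all(s1$condition[s1$phase != "main"] == "FULL"))
  s2 <- schedule_session(g, 2)
  expect_equal(nrow(s2), 1000)
  expect_true(all(s2$phase == "main"))
})

test_that("main-phase condition proportions are 1/2, 1/6, 1/6, 1/6", {
  set.seed(2)
  g <- group_config("uncorrelated")
  conds <- unlist(replicate(100, schedule_session(g, 2)$condition,
                            simplify = FALSE))
  n <- length(conds)  # 1e5 draws
  p_full <- mean(conds == "FULL")
  expect_lt(abs(p_full - 1 / 2), 3 * sqrt(0.5 * 0.5 / n))
  for (cc in c("PARTIAL_H", "PARTIAL_V", "NONE")) {
    expect_lt(abs(mean(conds == cc) - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / n))
  }
})

test_that("instructed-group insertions hit ~8% of trials and spare partial trials", {
  set.seed(3)
  g <- group_config("instructed")
  specs <- dplyr::bind_rows(replicate(50, schedule_session(g, 2),
                                      simplify = FALSE))
  rate <- mean(specs$uncorrelated_insertion)
  expect_lt(abs(rate - 0.08), 0.01)
  flagged <- which(specs$uncorrelated_insertion)
  expect_true(all(specs$condition[flagged] == "FULL"))
  nxt <- specs$condition[pmin(flagged + 1, nrow(specs))]
  expect_false(any(nxt %in% c("PARTIAL_H", "PARTIAL_V")))
  # other groups never flag
  set.seed(3)
  expect_false(any(schedule_session(group_config("correlated"), 2)$uncorrelated_insertion))
})

test_that("shift draws have the stated moments per regime", {
  set.seed(4)
  n <- 1e5
  g <- group_config("correlated")
  s <- draw_shift(g, "FULL", n = n)
  expect_lt(max(abs(colMeans(s) - c(-1, 1))), 3 / sqrt(n))
  expect_lt(abs(cor(s[, 1], s[, 2]) - (-0.999)), 0.005)
  su <- draw_shift(group_config("uncorrelated"), "FULL", n = n)
  expect_lt(abs(cor(su[, 1], su[, 2])), 0.01)
  # test trials are correlated for every group
  st <- draw_shift(group_config("uncorrelated"), "NONE", n = n)
  expect_lt(abs(cor(st[, 1], st[, 2]) - (-0.999)), 0.005)
  # training stage 1 has no shift
  expect_equal(draw_shift(g, "FULL", phase = "training_stage_1", n = 5),
               matrix(0, 5, 2))
  # flagged insertions are uncorrelated
  si <- draw_shift(group_config("instructed"), "FULL",
                   uncorrelated_insertion = TRUE, n = n)
  expect_lt(abs(cor(si[, 1], si[, 2])), 0.01)
})

test_that("hits require the cursor and target spheres to intersect", {
  expect_true(hit_test(c(0, 0)))
  expect_true(hit_test(c(0.79, 0)))
  expect_true(hit_test(c(0.8, 0)))       # boundary counts
  expect_false(hit_test(c(0.81, 0)))
  expect_equal(hit_test(rbind(c(0.5, 0.5), c(0.6, 0.6))), c(TRUE, FALSE))
})

test_that("participant records conserve counts and replay byte-identically", {
  rec <- simulate_participant(group_config("correlated"), actor_config(),
                              sessions = 2, trials_per_session = 300, seed = 7)
  expect_equal(nrow(rec), 600)
  expect_equal(unname(table(rec$session)), c(300L, 300L), ignore_attr = TRUE)
  expect_equal(rec$trial, 1:600)
  expect_true(all(rec$condition %in% FEEDBACK_CONDITIONS))
  # deviation = shift + response, hits follow the radius rule
  expect_equal(rec$hit, hit_test(cbind(rec$dev_h, rec$dev_v)))
  # prev_full tracks the most recent preceding full-feedback shift
  idx <- which(rec$condition == "FULL")
  after_first <- rec[rec$trial > min(idx), ]
  expect_true(all(is.finite(after_first$prev_full_s_h)))
  before_first <- rec[rec$trial <= min(idx), ]
  expect_true(all(!is.finite(before_first$prev_full_s_h)))
  k <- idx[5]
  nxt <- rec[rec$trial == k + 1, ]
  expect_equal(c(nxt$prev_full_s_h, nxt$prev_full_s_v),
               c(rec$s_h[k], rec$s_v[k]))
  rec2 <- simulate_participant(group_config("correlated"), actor_config(),
                               sessions = 2, trials_per_session = 300, seed = 7)
  expect_identical(as.data.frame(rec), as.data.frame(rec2))
})

test_that("test-trial shifts stay correlated across groups and conditions", {
  rec <- make_small_cohort(seed = 9, n_participants = 3, sessions = 2,
                           trials = 400, group = "uncorrelated")
  test_trials <- dplyr::filter(rec, condition %in% c("PARTIAL_H", "PARTIAL_V", "NONE"))
  expect_gt(nrow(test_trials), 500)
  expect_lt(cor(test_trials$s_h, test_trials$s_v), -0.99)
})

test_that("degenerate human-like config reproduces the plain learner", {
  cfg <- humanlike_config(motor_sd = 0, carryover = 0, base = "learner")
  a <- simulate_human_like(group_config("correlated"), cfg, "p", sessions = 1,
                           trials_per_session = 200, seed = 13)
  b <- simulate_participant(group_config("correlated"), actor_config(), "p",
                            sessions = 1, trials_per_session = 200, seed = 13)
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("motor noise inflates no-feedback endpoint variance", {
  base <- simulate_human_like(group_config("correlated"),
                              humanlike_config(motor_sd = 0), "p",
                              sessions = 1, trials_per_session = 600, seed = 14)
  noisy <- simulate_human_like(group_config("correlated"),
                               humanlike_config(motor_sd = 0.5), "p",
                               sessions = 1, trials_per_session = 600, seed = 14)
  v0 <- var(dplyr::filter(base, condition == "NONE")$dev_h)
  v1 <- var(dplyr::filter(noisy, condition == "NONE")$dev_h)
  expect_gt(v1, v0)
})
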