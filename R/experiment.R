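
#' Study group configurations
#'
#' Four groups differ only in their training statistics and feedback
#' scheduling: the correlated group trains on shifts with `rho = -0.999`,
#' the uncorrelated group on `rho = 0`; the no-auditory group is a
#' correlated group without hit/miss sounds in partial- and no-feedback
#' trials (recorded as a flag — the model has no reward pathway); the
#' instructed group is a correlated group in which roughly 8% of all trials
#' are uncorrelated full-feedback trials inserted immediately before
#' no-feedback trials. Test trials (partial and no feedback) draw from the
#' correlated distribution (`rho = -0.999`) in every group.
#'
#' @param name One of `"correlated"`, `"uncorrelated"`, `"no_auditory"`,
#'   `"instructed"`.
#' @return An `sb_group` list with `name`, `rho_train`, `rho_test`,
#'   `auditory_feedback_in_test` and `instructed_insertions`.
#' @examples
#' group_config("uncorrelated")$rho_train  # 0
#' @export
group_config <- function(name = c("correlated", "uncorrelated",
                                  "no_auditory", "instructed")) {
  name <- match.arg(name)
  structure(list(
    name = name,
    rho_train = if (name == "uncorrelated") 0 else -0.999,
    rho_test = -0.999,
    auditory_feedback_in_test = name != "no_auditory",
    instructed_insertions = name == "instructed"
  ), class = "sb_group")
}

# Study design constants: 4 sessions x 1000 trials, session 1 leads with a
# 50/50/100 three-stage full-feedback training phase; main-phase conditions
# are drawn independently with P(FULL) = 1/2 and 1/6 each for PARTIAL_H,
# PARTIAL_V, NONE. Hit radius = cursor radius 0.3 cm + target radius 0.5 cm.
# Workspace metadata (not used in deviation coordinates): start sphere at
# z = 0.5 cm, target plane at z = 14 cm, extents +-5 cm.
study_design <- function() {
  list(sessions = 4L, trials_per_session = 1000L,
       training_stages = c(stage1 = 50L, stage2 = 50L, stage3 = 100L),
       condition_probs = c(FULL = 1 / 2, PARTIAL_H = 1 / 6,
                           PARTIAL_V = 1 / 6, NONE = 1 / 6),
       hit_radius = 0.8,
       insertion_rate = 0.08,
       mu = c(-1, 1), sigma = c(1, 1),
       workspace = list(start_z = 0.5, target_z = 14, extent = 5))
}

#' Schedule the trials of one session
#'
#' Produces the ordered trial specifications of a session: session 1 opens
#' with the three training stages (50 no-shift trials with a veridical
#' cursor, 50 fully visible shifted-cursor trials, 100 ordinary
#' full-feedback trials) followed by 800 main-phase trials; later sessions
#' are 1000 main-phase trials. Main-phase conditions are independent draws
#' with probability 1/2 for full feedback and 1/6 for each other condition.
#' For the instructed group, each full-feedback trial that immediately
#' precedes a no-feedback trial is flagged to carry an uncorrelated shift
#' with probability 0.96, so flagged trials make up about 8% of all trials
#' while never preceding a partial-feedback trial.
#'
#' @param group An [group_config()].
#' @param session Session number.
#' @param trials_per_session Trials per session (default 1000; smaller
#'   values give scaled-down sessions with the same training-phase layout).
#' @return A tibble with columns `session`, `index`, `phase` (one of
#'   `training_stage_1/2/3`, `main`), `condition`, `uncorrelated_insertion`.
#' @export
schedule_session <- function(group, session, trials_per_session = 1000L) {
  stopifnot(inherits(group, "sb_group"), session >= 1)
  des <- study_design()
  n <- as.integer(trials_per_session)
  if (session == 1L) {
    st <- des$training_stages
    if (n < des$trials_per_session) {  # scaled-down sessions shrink stages proportionally
      st <- pmax(1L, as.integer(round(st * n / des$trials_per_session)))
    }
    phase <- c(rep("training_stage_1", st[1]), rep("training_stage_2", st[2]),
               rep("training_stage_3", st[3]))
    n_main <- n - length(phase)
  } else {
    phase <- character(0)
    n_main <- n
  }
  cond_main <- sample(names(des$condition_probs), n_main, replace = TRUE,
                      prob = des$condition_probs)
  n_train <- length(phase)
  spec <- tibble::tibble(
    session = as.integer(session),
    index = seq_len(n_train + n_main),
    phase = c(phase, rep("main", n_main)),
    condition = c(rep("FULL", n_train), cond_main),
    uncorrelated_insertion = FALSE
  )
  if (group$instructed_insertions) {
    before_none <- which(spec$condition == "FULL" &
                           dplyr::lead(spec$condition) == "NONE" &
                           spec$phase == "main")
    p_flag <- min(1, des$insertion_rate /
                    (des$condition_probs[["FULL"]] * des$condition_probs[["NONE"]]))
    flag <- before_none[stats::runif(length(before_none)) < p_flag]
    spec$uncorrelated_insertion[flag] <- TRUE
  }
  spec
}

#' Draw a trial's true shift
#'
#' Training-stage-1 trials carry no shift. Full-feedback trials in the main
#' phase and training stages 2-3 draw from the group's training
#' distribution; partial- and no-feedback trials always draw from the
#' correlated test distribution. Flagged instructed-group insertions
#' override the correlation to zero. The mean is `(-1, +1)` cm with unit
#' standard deviations throughout.
#'
#' @param group An [group_config()].
#' @param condition One of [FEEDBACK_CONDITIONS].
#' @param phase Trial phase string (see [schedule_session()]).
#' @param uncorrelated_insertion Flag from the schedule.
#' @param n Number of shifts to draw.
#' @return An `n x 2` matrix of shifts (cm).
#' @export
draw_shift <- function(group, condition, phase = "main",
                       uncorrelated_insertion = FALSE, n = 1) {
  stopifnot(inherits(group, "sb_group"))
  check_condition(condition)
  if (phase == "training_stage_1") return(matrix(0, n, 2))
  des <- study_design()
  rho <- if (condition == "FULL") group$rho_train else group$rho_test
  if (uncorrelated_insertion) rho <- 0
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(des$mu[1] + des$sigma[1] * z1,
        des$mu[2] + des$sigma[2] * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Hit determination
#'
#' A trial is a hit when the final cursor (radius 0.3 cm, centred at the
#' shifted hand position) intersects the target sphere (radius 0.5 cm):
#' the terminal deviation's Euclidean norm is at most 0.8 cm, boundary
#' included.
#'
#' @param deviation Terminal deviation(s) from target centre: length-2
#'   vector or `n x 2` matrix, cm.
#' @return Logical vector.
#' @examples
#' hit_test(c(0.5, 0.5))   # TRUE: norm ~ 0.71 cm
#' hit_test(c(0.81, 0))    # FALSE
#' @export
hit_test <- function(deviation) {
  if (is.null(dim(deviation))) deviation <- matrix(as.numeric(deviation), ncol = 2)
  stopifnot(all(is.finite(deviation)))
  sqrt(rowSums(deviation^2)) <= study_design()$hit_radius
}

empty_records <- function() {
  tibble::tibble(
    participant = character(), group = character(), session = integer(),
    trial = integer(), phase = character(), condition = character(),
    s_h = double(), s_v = double(), d_h = double(), d_v = double(),
    dev_h = double(), dev_v = double(), hit = logical(),
    prev_full_s_h = double(), prev_full_s_v = double()
  )
}

#' Simulate one model-driven virtual participant
#'
#' Runs the full study for a single participant of the sampling-learner
#' model: schedules every session, draws the true shifts, presents the
#' feedback point (the true shifted position, seen through the actor's
#' condition-dependent noise model), obtains the bounded-rational response
#' via [respond()], updates the learner's NIW belief after every
#' full-feedback trial, and records terminal deviations, hits, and the
#' shift of the most recent preceding full-feedback trial.
#'
#' Terminal deviation is `true shift + response` in deviation coordinates
#' (target centre at the origin), so ideal compensation gives the zero
#' vector.
#'
#' @param group An [group_config()].
#' @param config An [actor_config()].
#' @param participant Participant identifier string.
#' @param sessions Number of sessions (default 4).
#' @param trials_per_session Trials per session (default 1000).
#' @param seed Optional integer seed for this participant's private stream.
#' @return A tibble of trial records (one row per trial) with the columns
#'   of the canonical record table; see [write_trial_records()].
#' @export
simulate_participant <- function(group, config = actor_config(),
                                 participant = "vp1",
                                 sessions = 4L, trials_per_session = 1000L,
                                 seed = NULL) {
  stopifnot(inherits(group, "sb_group"), inherits(config, "sb_actor_config"))
  if (!is.null(seed)) set.seed(seed)
  state <- config$state
  recs <- vector("list", sessions)
  trial0 <- 0L
  for (ses in seq_len(sessions)) {
    spec <- schedule_session(group, ses, trials_per_session)
    nt <- nrow(spec)
    s <- matrix(NA_real_, nt, 2)
    dev <- matrix(NA_real_, nt, 2)
    dpt <- matrix(NA_real_, nt, 2)
    prev <- matrix(NA_real_, nt, 2)
    last_full <- attr(state, "last_full") %||% c(NA_real_, NA_real_)
    for (i in seq_len(nt)) {
      cond <- spec$condition[i]
      s[i, ] <- draw_shift(group, cond, spec$phase[i],
                           spec$uncorrelated_insertion[i])
      prev[i, ] <- last_full
      training <- spec$phase[i] != "main"
      if (spec$phase[i] %in% c("training_stage_1", "training_stage_2")) {
        # cursor visible throughout: the shift is fully observable and
        # compensable, response cancels it exactly
        resp <- -s[i, ]
      } else {
        resp <- respond(state, s[i, ], cond, config)$response
      }
      dev[i, ] <- s[i, ] + resp
      if (cond != "NONE") dpt[i, ] <- s[i, ]
      if (cond == "FULL") {
        last_full <- s[i, ]
        if (!training || config$train_during_training_phase) {
          state <- train_on_trial(state, s[i, ])
        }
      }
    }
    attr(state, "last_full") <- last_full
    recs[[ses]] <- tibble::tibble(
      participant = participant, group = group$name,
      session = spec$session, trial = trial0 + spec$index,
      phase = spec$phase, condition = spec$condition,
      s_h = s[, 1], s_v = s[, 2], d_h = dpt[, 1], d_v = dpt[, 2],
      dev_h = dev[, 1], dev_v = dev[, 2],
      hit = hit_test(dev),
      prev_full_s_h = prev[, 1], prev_full_s_v = prev[, 2]
    )
    trial0 <- trial0 + nt
  }
  out <- dplyr::bind_rows(recs)
  attr(out, "final_state") <- state
  out
}

#' Human-like participant configuration
#'
#' A noise-augmented stand-in participant used to exercise the analysis
#' pipeline with known ground truth: a base actor (the ideal Bayesian actor
#' with full knowledge of the task statistics, or the sampling learner)
#' plus isotropic Gaussian motor noise on every response and, in
#' no-feedback trials, a carryover term proportional to the shift of the
#' preceding full-feedback trial.
#'
#' @param motor_sd Isotropic motor-noise SD, cm (>= 0).
#' @param carryover Weight on the previous full-feedback shift in
#'   no-feedback responses, dimensionless, `|carryover| <= 1`.
#' @param base `"ideal"` or `"learner"`.
#' @param actor [actor_config()] used when `base = "learner"`.
#' @return An `sb_humanlike` list.
#' @export
humanlike_config <- function(motor_sd = 0, carryover = 0,
                             base = c("ideal", "learner"),
                             actor = actor_config()) {
  stopifnot(motor_sd >= 0, abs(carryover) <= 1)
  structure(list(motor_sd = motor_sd, carryover = carryover,
                 base = match.arg(base), actor = actor),
            class = "sb_humanlike")
}

#' Simulate a human-like participant
#'
#' As [simulate_participant()], but responses get isotropic motor noise
#' added and no-feedback responses additionally carry over a fraction of
#' the previous full-feedback shift. With the `"ideal"` base the actor
#' responds with minus the posterior mean under the true task statistics
#' (training distribution for full-feedback trials, test distribution
#' otherwise) rather than by sampling. Ground-truth parameters are attached
#' as the `"ground_truth"` attribute for recovery tests.
#'
#' @inheritParams simulate_participant
#' @param cfg An [humanlike_config()].
#' @return A trial-record tibble.
#' @export
simulate_human_like <- function(group, cfg = humanlike_config(),
                                participant = "hp1",
                                sessions = 4L, trials_per_session = 1000L,
                                seed = NULL) {
  stopifnot(inherits(group, "sb_group"), inherits(cfg, "sb_humanlike"))
  if (!is.null(seed)) set.seed(seed)
  if (cfg$base == "learner") {
    out <- simulate_participant(group, cfg$actor, participant,
                                sessions, trials_per_session)
    out <- perturb_records(out, cfg)
  } else {
    out <- simulate_ideal(group, cfg, participant, sessions, trials_per_session)
  }
  attr(out, "ground_truth") <- list(motor_sd = cfg$motor_sd,
                                    carryover = cfg$carryover, base = cfg$base)
  out
}

# ideal base: responds -mu_p under the true statistics, exact-limit noise
simulate_ideal <- function(group, cfg, participant, sessions, trials_per_session) {
  prof <- noise_profile(low = 0.2, high = Inf)
  prior_train <- shift_distribution(rho = min(group$rho_train, 0.999))
  prior_test <- shift_distribution(rho = group$rho_test)
  recs <- vector("list", sessions)
  trial0 <- 0L
  last_full <- c(NA_real_, NA_real_)
  for (ses in seq_len(sessions)) {
    spec <- schedule_session(group, ses, trials_per_session)
    nt <- nrow(spec)
    s <- dev <- dpt <- prev <- matrix(NA_real_, nt, 2)
    for (i in seq_len(nt)) {
      cond <- spec$condition[i]
      s[i, ] <- draw_shift(group, cond, spec$phase[i],
                           spec$uncorrelated_insertion[i])
      prev[i, ] <- last_full
      prior <- if (cond == "FULL") prior_train else prior_test
      if (spec$phase[i] %in% c("training_stage_1", "training_stage_2")) {
        resp <- -s[i, ]
      } else if (cond == "NONE") {
        resp <- -prior$mu
        if (cfg$carryover != 0 && all(is.finite(prev[i, ]))) {
          resp <- resp + cfg$carryover * prev[i, ]
        }
      } else {
        resp <- ideal_response(posterior_belief(prior,
                                                condition_noise(cond, prof),
                                                s[i, ]))
      }
      if (cfg$motor_sd > 0) resp <- resp + stats::rnorm(2, 0, cfg$motor_sd)
      dev[i, ] <- s[i, ] + resp
      if (cond != "NONE") dpt[i, ] <- s[i, ]
      if (cond == "FULL") last_full <- s[i, ]
    }
    recs[[ses]] <- tibble::tibble(
      participant = participant, group = group$name,
      session = spec$session, trial = trial0 + spec$index,
      phase = spec$phase, condition = spec$condition,
      s_h = s[, 1], s_v = s[, 2], d_h = dpt[, 1], d_v = dpt[, 2],
      dev_h = dev[, 1], dev_v = dev[, 2], hit = hit_test(dev),
      prev_full_s_h = prev[, 1], prev_full_s_v = prev[, 2]
    )
    trial0 <- trial0 + nt
  }
  dplyr::bind_rows(recs)
}

# add motor noise / carryover to an existing record table (learner base)
perturb_records <- function(records, cfg) {
  n <- nrow(records)
  if (cfg$motor_sd > 0) {
    records$dev_h <- records$dev_h + stats::rnorm(n, 0, cfg$motor_sd)
    records$dev_v <- records$dev_v + stats::rnorm(n, 0, cfg$motor_sd)
  }
  if (cfg$carryover != 0) {
    i <- records$condition == "NONE" & is.finite(records$prev_full_s_h)
    records$dev_h[i] <- records$dev_h[i] + cfg$carryover * records$prev_full_s_h[i]
    records$dev_v[i] <- records$dev_v[i] + cfg$carryover * records$prev_full_s_v[i]
  }
  records$hit <- hit_test(cbind(records$dev_h, records$dev_v))
  records
}

#' Simulate a cohort of virtual participants
#'
#' Runs several participants of one group with independent, replayable
#' seed streams derived from a single top-level seed: stream `i` is a
#' fixed multiplicative hash of `(seed, i)`, recorded in run manifests so
#' any participant can be replayed in isolation.
#'
#' @inheritParams simulate_participant
#' @param n_participants Number of virtual participants (study: 6).
#' @param seed Top-level integer seed.
#' @param humanlike Optional [humanlike_config()]; when supplied,
#'   participants are simulated with [simulate_human_like()].
#' @return A single trial-record tibble for the whole cohort, participants
#'   labelled `"<group>_vp<i>"`.
#' @export
simulate_cohort <- function(group, config = actor_config(),
                            n_participants = 6L, seed = 1L,
                            sessions = 4L, trials_per_session = 1000L,
                            humanlike = NULL) {
  stopifnot(inherits(group, "sb_group"))
  runs <- purrr::map(seq_len(n_participants), function(i) {
    pid <- sprintf("%s_vp%d", group$name, i)
    ps <- participant_seed(seed, i)
    if (is.null(humanlike)) {
      simulate_participant(group, config, pid, sessions, trials_per_session,
                           seed = ps)
    } else {
      simulate_human_like(group, humanlike, pid, sessions, trials_per_session,
                          seed = ps)
    }
  })
  dplyr::bind_rows(runs)
}
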