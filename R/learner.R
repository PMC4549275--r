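
#' Normal-inverse-Wishart belief state
#'
#' The hierarchical learner's belief over the shift distribution's mean and
#' covariance is a normal-inverse-Wishart (NIW) distribution over the
#' parameters `(psi, Theta)` of the Gaussian that generates full-feedback
#' observations (`Theta` subsumes the feedback noise). Its hyper-parameters
#' are a location `m` (cm), pseudo-count weights `kappa` (on the mean) and
#' `nu` (on the covariance), and a scale matrix `S` (cm^2 times counts).
#'
#' The study's initial state is `m = (0, 0)`, `kappa = 300`, `nu = 3000`,
#' `S = diag(nu, nu)` — a diagonal initial covariance belief with unit
#' variance per dimension (no correlation), weighted like 3000 prior
#' observations.
#'
#' @param m Numeric length-2 location, cm.
#' @param kappa Positive pseudo-count on the mean.
#' @param nu Degrees of freedom, `> 1` (dimension minus one).
#' @param S Symmetric positive-definite 2x2 scale matrix.
#' @param trials_seen Number of observations absorbed so far (bookkeeping).
#' @return An `sb_niw` object.
#' @examples
#' niw_state()             # the study's initial belief
#' niw_state(kappa = 5, nu = 10, S = diag(10, 2))
#' @export
niw_state <- function(m = c(0, 0), kappa = 300, nu = 3000,
                      S = diag(nu, 2), trials_seen = 0L) {
  m <- as_len2(m, "m")
  stopifnot(kappa > 0, nu > 1)
  check_sym_psd(S, "S")
  if (!is_pd2(S[1, 1], S[1, 2], S[2, 2])) {
    stop("`S` must be positive definite", call. = FALSE)
  }
  structure(list(m = m, kappa = kappa, nu = nu, S = S,
                 trials_seen = as.integer(trials_seen)),
            class = "sb_niw")
}

#' @export
print.sb_niw <- function(x, ...) {
  cat(sprintf("<NIW state> m = (%.4g, %.4g), kappa = %g, nu = %g, trials seen = %d\n",
              x$m[1], x$m[2], x$kappa, x$nu, x$trials_seen))
  cat("  S:\n"); print(round(x$S, 4))
  invisible(x)
}

#' Conjugate NIW update from a batch of observations
#'
#' Absorbs `N` observed shifts into the NIW belief with the closed-form
#' conjugate update: the location moves to the pseudo-count-weighted average
#' of the old location and the empirical mean, both pseudo-counts grow by
#' `N`, and the scale matrix accumulates the empirical scatter plus a
#' between-means term:
#' \deqn{m_N = (\kappa_0 m_0 + N \bar D)/\kappa_N,\quad
#'       \kappa_N = \kappa_0 + N,\quad \nu_N = \nu_0 + N,}
#' \deqn{S_N = S_0 + S_{\bar D} +
#'       \frac{\kappa_0 N}{\kappa_0 + N}(\bar D - m_0)(\bar D - m_0)^T.}
#' Sequential single-observation updates and one batch call commute: any
#' ordering of the data yields the same posterior.
#'
#' @param state An [niw_state()].
#' @param data Observations: a numeric length-2 vector, an `N x 2` matrix,
#'   or a list of length-2 vectors (cm).
#' @return The updated `sb_niw` state.
#' @export
niw_update_batch <- function(state, data) {
  stopifnot(inherits(state, "sb_niw"))
  if (is.list(data) && !is.data.frame(data)) data <- do.call(rbind, data)
  if (is.null(dim(data))) data <- matrix(as.numeric(data), ncol = 2)
  data <- as.matrix(data)
  if (nrow(data) == 0L) stop("`data` must contain at least one observation", call. = FALSE)
  if (ncol(data) != 2L || !all(is.finite(data))) {
    stop("`data` must be finite with two columns (h, v)", call. = FALSE)
  }
  N    <- nrow(data)
  dbar <- colMeans(data)
  ctr  <- sweep(data, 2, dbar)
  S_d  <- crossprod(ctr)
  kN   <- state$kappa + N
  dm   <- dbar - state$m
  SN   <- state$S + S_d + (state$kappa * N / kN) * tcrossprod(dm)
  niw_state(m = (state$kappa * state$m + N * dbar) / kN,
            kappa = kN, nu = state$nu + N, S = SN,
            trials_seen = state$trials_seen + N)
}

#' @rdname niw_update_batch
#' @param d A single observed shift, numeric length-2 (cm). Called once per
#'   full-feedback trial; the learner trains on full-feedback trials only.
#' @export
train_on_trial <- function(state, d) {
  niw_update_batch(state, matrix(as_len2(d, "d"), 1))
}

#' Peak of the feedback likelihood
#'
#' The rejection sampler normalises the acceptance ratio by the maximum of
#' the Gaussian feedback likelihood, its density at the mean:
#' `1 / (2 * pi * sqrt(det(Sigma_obs)))`. Requires finite variances — the
#' no-feedback condition uses the finite 40 cm^2 stand-in.
#'
#' @param noise An [obs_noise()] with finite entries.
#' @return Positive scalar, the peak density (cm^-2).
#' @export
likelihood_max <- function(noise) {
  if (!is.finite(noise$var_h) || !is.finite(noise$var_v)) {
    stop("likelihood_max() needs finite feedback variances; use the finite high-variance stand-in",
         call. = FALSE)
  }
  1 / (2 * pi * sqrt(noise$var_h * noise$var_v))
}

#' Actor configuration
#'
#' Bundles everything that defines a simulated participant's internal model:
#' the initial NIW state, the feedback-noise profile the model assumes
#' (`low = 0.2`, `high = 40` cm^2), the rejection-loop iteration cap, the
#' numerical floor for the positive-definiteness gate, whether the
#' no-feedback acceptance step is performed against the (unseen) true
#' shifted position or skipped, and whether the learner also trains on the
#' session-1 training-stage trials.
#'
#' @param state Initial [niw_state()]; defaults to the study values.
#' @param profile [noise_profile()] the actor assumes; must be finite.
#' @param max_iter Rejection-loop cap per trial.
#' @param psd_floor Eigenvalue floor for accepting a sampled prior
#'   covariance (guards numerically zero eigenvalues).
#' @param none_acceptance `"nominal_d"` (default): in no-feedback trials run
#'   the acceptance step against the true shifted position with the high
#'   variance, which is nearly flat; `"skip"`: accept the first prior sample.
#' @param train_during_training_phase Update the NIW state from session-1
#'   training-stage full-feedback trials (default `TRUE`).
#' @param on_cap What to do when the rejection loop exhausts `max_iter`
#'   proposals without an acceptance, which happens when the feedback point
#'   lies far in the prior-predictive tail so the per-proposal acceptance
#'   probability is astronomically small. `"equivalent"` (default) finishes
#'   the trial with the distribution-preserving shortcut: because the loop
#'   is memoryless, the accepted sample's law does not depend on how many
#'   proposals were consumed, so a hyper-parameter draw importance-resampled
#'   by its marginal acceptance probability followed by an exact draw from
#'   the closed-form conjugate posterior yields the same response
#'   distribution. `"error"` aborts the trial instead.
#' @return An `sb_actor_config` list.
#' @export
actor_config <- function(state = niw_state(),
                         profile = noise_profile(),
                         max_iter = 1e6,
                         psd_floor = 1e-12,
                         none_acceptance = c("nominal_d", "skip"),
                         train_during_training_phase = TRUE,
                         on_cap = c("equivalent", "error")) {
  stopifnot(inherits(state, "sb_niw"),
            is.finite(profile$low), is.finite(profile$high), max_iter >= 1)
  structure(list(state = state, profile = profile,
                 max_iter = max_iter, psd_floor = psd_floor,
                 none_acceptance = match.arg(none_acceptance),
                 train_during_training_phase = isTRUE(train_during_training_phase),
                 on_cap = match.arg(on_cap)),
            class = "sb_actor_config")
}

# --- vectorised NIW draws -------------------------------------------------

# Draw n samples (Theta, psi) from NIW(m, kappa, nu, S) using the Bartlett
# decomposition of the Wishart(nu, S^-1) whose inverse is Theta.
# Returns a list of numeric vectors: Theta entries (t11, t12, t22) and psi
# (p1, p2). All 2x2 algebra is scalar-vectorised for speed.
niw_draw_n <- function(n, m, kappa, nu, S) {
  iv <- inv2(S[1, 1], S[1, 2], S[2, 2])        # V = S^-1
  L  <- chol2(iv[1], iv[2], iv[3])             # V = L L^T (lower)
  a11 <- sqrt(stats::rchisq(n, nu))
  a21 <- stats::rnorm(n)
  a22 <- sqrt(stats::rchisq(n, nu - 1))
  # B = L A (lower triangular), W = B B^T ~ Wishart(nu, V)
  b11 <- L[1] * a11
  b21 <- L[2] * a11 + L[3] * a21
  b22 <- L[3] * a22
  w11 <- b11 * b11
  w12 <- b11 * b21
  w22 <- b21 * b21 + b22 * b22
  dW  <- w11 * w22 - w12 * w12
  t11 <- w22 / dW                               # Theta = W^-1 ~ IW(nu, S)
  t12 <- -w12 / dW
  t22 <- w11 / dW
  # psi ~ N(m, Theta / kappa): lower Cholesky of Theta, scaled
  c11 <- sqrt(t11 / kappa)
  c21 <- (t12 / kappa) / c11
  c22 <- sqrt(pmax(t22 / kappa - c21 * c21, 0))
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  list(t11 = t11, t12 = t12, t22 = t22,
       p1 = m[1] + c11 * z1,
       p2 = m[2] + c21 * z1 + c22 * z2)
}

#' Sample shift-distribution hyper-parameters from the NIW belief
#'
#' Draws `(psi, Theta)` from the NIW posterior, converts them to the
#' parameters of the prior over the shift by removing the subsumed
#' full-feedback observation noise (`mu0 = psi`,
#' `Sigma0 = Theta - Sigma_obs`), and resamples until `Sigma0` is positive
#' (semi-)definite — the PSD gate. The full-feedback noise is always the one
#' subtracted, because the belief is trained on full-feedback trials only.
#'
#' @param state An [niw_state()].
#' @param obs_noise_full The FULL-condition [obs_noise()] (finite).
#' @param max_iter Resampling cap before erroring (an exceeded cap signals
#'   an ill-posed state, e.g. `S` too small relative to the noise).
#' @param psd_floor Strict eigenvalue floor for acceptance.
#' @return A list with `mu0` (length-2, cm), `Sigma0` (2x2, cm^2) and
#'   `rejections` (number of discarded draws).
#' @export
sample_hyperparameters <- function(state, obs_noise_full = condition_noise("FULL"),
                                   max_iter = 1e6, psd_floor = 1e-12) {
  stopifnot(inherits(state, "sb_niw"))
  if (!is.finite(obs_noise_full$var_h) || !is.finite(obs_noise_full$var_v)) {
    stop("`obs_noise_full` must be finite", call. = FALSE)
  }
  rejections <- 0L
  block <- 16L
  repeat {
    dr <- niw_draw_n(block, state$m, state$kappa, state$nu, state$S)
    s11 <- dr$t11 - obs_noise_full$var_h
    s12 <- dr$t12
    s22 <- dr$t22 - obs_noise_full$var_v
    ok <- is_pd2(s11, s12, s22, floor = psd_floor)
    i <- which(ok)
    if (length(i)) {
      i <- i[1]
      rejections <- rejections + i - 1L
      return(list(mu0 = c(dr$p1[i], dr$p2[i]),
                  Sigma0 = matrix(c(s11[i], s12[i], s12[i], s22[i]), 2, 2),
                  rejections = rejections))
    }
    rejections <- rejections + block
    if (rejections >= max_iter) {
      stop(sprintf(paste0("PSD gate rejected %d consecutive hyper-parameter draws; ",
                          "state (kappa = %g, nu = %g) is ill-posed relative to the feedback noise"),
                   rejections, state$kappa, state$nu), call. = FALSE)
    }
    block <- min(block * 2L, 4096L)
  }
}

#' Bounded-rational response by rejection sampling
#'
#' Simulates one trial of the sampling actor. Each rejection-loop iteration
#' draws fresh hyper-parameters from the NIW belief (restarting at the first
#' step, as the scheme prescribes), gates them for positive definiteness,
#' draws a candidate shift from the implied prior, and accepts it with
#' probability equal to the feedback likelihood over its peak,
#' `p(d | s) / l_max`. The response is minus the first accepted shift.
#'
#' In no-feedback trials the acceptance step uses the finite high-variance
#' noise and, under the default configuration, the true shifted position as
#' the nominal feedback point; with 40 cm^2 variance the step is nearly
#' flat, so this choice is behaviourally negligible (see
#' [actor_config()]).
#'
#' @param state An [niw_state()].
#' @param d Feedback point (cm). For `NONE` trials pass the true shifted
#'   position (used only as the nominal acceptance anchor) or `NULL` when
#'   `none_acceptance = "skip"`.
#' @param condition One of [FEEDBACK_CONDITIONS].
#' @param config An [actor_config()].
#' @return A list: `response` (length-2 cm, equals `-shift`), `shift` (the
#'   accepted sampled shift), `iterations` (rejection-loop iterations
#'   consumed, including PSD-gate restarts).
#' @export
respond <- function(state, d, condition, config = actor_config()) {
  check_condition(condition)
  stopifnot(inherits(state, "sb_niw"))
  noise <- condition_noise(condition, config$profile)
  skip_accept <- condition == "NONE" && config$none_acceptance == "skip"
  if (is.null(d)) {
    if (!skip_accept) {
      stop("`d` is required unless none_acceptance = \"skip\" in a NONE trial",
           call. = FALSE)
    }
    d <- c(0, 0)
  }
  d <- as_len2(d, "d")
  full <- condition_noise("FULL", config$profile)
  floor <- config$psd_floor
  inv_vh <- 1 / noise$var_h
  inv_vv <- 1 / noise$var_v
  used <- 0
  block <- 32L
  repeat {
    dr <- niw_draw_n(block, state$m, state$kappa, state$nu, state$S)
    s11 <- dr$t11 - full$var_h
    s12 <- dr$t12
    s22 <- dr$t22 - full$var_v
    ok <- is_pd2(s11, s12, s22, floor = floor)
    # candidate shift from N(mu0, Sigma0) where the gate passed
    c11 <- sqrt(ifelse(ok, s11, 1))
    c21 <- ifelse(ok, s12, 0) / c11
    c22 <- sqrt(pmax(ifelse(ok, s22, 1) - c21 * c21, 0))
    z1 <- stats::rnorm(block); z2 <- stats::rnorm(block)
    sh <- dr$p1 + c11 * z1
    sv <- dr$p2 + c21 * z1 + c22 * z2
    if (skip_accept) {
      acc <- ok
    } else {
      # p(d|s)/l_max = exp(-((d_h - s_h)^2/var_h + (d_v - s_v)^2/var_v)/2)
      logratio <- -0.5 * ((d[1] - sh)^2 * inv_vh + (d[2] - sv)^2 * inv_vv)
      acc <- ok & (log(stats::runif(block)) <= logratio)
    }
    i <- which(acc)
    if (length(i)) {
      i <- i[1]
      s <- c(sh[i], sv[i])
      return(list(response = -s, shift = s, iterations = used + i))
    }
    used <- used + block
    if (used >= config$max_iter) {
      if (config$on_cap == "error") {
        stop(sprintf("rejection loop exceeded %g iterations in a %s trial",
                     config$max_iter, condition), call. = FALSE)
      }
      s <- equivalent_draw(state, d, noise, full, floor)
      return(list(response = -s, shift = s, iterations = used))
    }
    block <- min(block * 2L, 8192L)
  }
}

# Distribution-preserving completion of a capped rejection loop: the
# accepted (hyper, shift) pair has density proportional to
#   NIW_gated(mu0, Sigma0) * N(d; mu0, Sigma0 + Sigma_obs)
#     * N(s; mu_p(mu0, Sigma0, d), Sigma_p(mu0, Sigma0)),
# so a gated hyper draw importance-resampled by the marginal acceptance
# weight N(d; mu0, Sigma0 + Sigma_obs), followed by an exact draw from the
# conjugate posterior, has the same law as the loop's accepted sample
# (exactly as the resampling pool grows; with the study's pseudo-counts the
# weights are nearly constant across draws, so a moderate pool is ample).
equivalent_draw <- function(state, d, noise, full, floor, pool = 4096L) {
  dr <- niw_draw_n(pool, state$m, state$kappa, state$nu, state$S)
  s11 <- dr$t11 - full$var_h
  s12 <- dr$t12
  s22 <- dr$t22 - full$var_v
  ok <- is_pd2(s11, s12, s22, floor = floor)
  if (!any(ok)) {
    stop("PSD gate rejected an entire resampling pool; the belief state is ill-posed",
         call. = FALSE)
  }
  # log weight: log N(d; mu0, Sigma0 + Sigma_obs_condition), gated draws only
  a <- s11[ok] + noise$var_h
  b <- s12[ok]
  cc <- s22[ok] + noise$var_v
  dt <- a * cc - b * b
  rh <- d[1] - dr$p1[ok]
  rv <- d[2] - dr$p2[ok]
  logw <- -0.5 * log(dt) - 0.5 * (cc * rh^2 - 2 * b * rh * rv + a * rv^2) / dt
  w <- exp(logw - max(logw))
  i <- sample.int(length(w), 1L, prob = w)
  mu0 <- c(dr$p1[ok][i], dr$p2[ok][i])
  Sigma0 <- matrix(c(s11[ok][i], s12[ok][i], s12[ok][i], s22[ok][i]), 2, 2)
  iS <- inv2(Sigma0[1, 1], Sigma0[1, 2], Sigma0[2, 2])
  Ppost <- matrix(c(iS[1] + 1 / noise$var_h, iS[2],
                    iS[2], iS[3] + 1 / noise$var_v), 2, 2)
  iv <- inv2(Ppost[1, 1], Ppost[1, 2], Ppost[2, 2])
  Sp <- matrix(c(iv[1], iv[2], iv[2], iv[3]), 2, 2)
  mp <- drop(Sp %*% (c(d[1] / noise$var_h, d[2] / noise$var_v) +
                       matrix(c(iS[1], iS[2], iS[2], iS[3]), 2, 2) %*% mu0))
  L <- chol2(Sp[1, 1], Sp[1, 2], Sp[2, 2])
  z <- stats::rnorm(2)
  c(mp[1] + L[1] * z[1], mp[2] + L[2] * z[1] + L[3] * z[2])
}

#' Rejection sampling from a fixed shift prior
#'
#' Runs only the shift-sampling and acceptance steps of the actor's scheme
#' for a fixed hyper-parameter sample `(mu0, Sigma0)`, returning `n`
#' accepted shifts. For a Gaussian prior and Gaussian likelihood the
#' accepted-sample distribution is exactly the closed-form conjugate
#' posterior ([posterior_belief()]), which makes this the test surface for
#' sampler correctness.
#'
#' @param mu0 Prior mean, length-2, cm.
#' @param Sigma0 Prior covariance, 2x2, positive definite, cm^2.
#' @param noise Finite [obs_noise()].
#' @param d Feedback point, length-2, cm.
#' @param n Number of accepted samples to return.
#' @param max_iter Total-proposal cap.
#' @return An `n x 2` matrix of accepted shifts (cm).
#' @export
rejection_sample_shift <- function(mu0, Sigma0, noise, d, n = 1,
                                   max_iter = 1e8) {
  mu0 <- as_len2(mu0, "mu0")
  d <- as_len2(d, "d")
  check_sym_psd(Sigma0, "Sigma0")
  stopifnot(is.finite(noise$var_h), is.finite(noise$var_v))
  L <- chol2(Sigma0[1, 1], Sigma0[1, 2], Sigma0[2, 2])
  inv_vh <- 1 / noise$var_h
  inv_vv <- 1 / noise$var_v
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  used <- 0
  block <- max(256L, n)
  repeat {
    z1 <- stats::rnorm(block); z2 <- stats::rnorm(block)
    sh <- mu0[1] + L[1] * z1
    sv <- mu0[2] + L[2] * z1 + L[3] * z2
    acc <- log(stats::runif(block)) <=
      -0.5 * ((d[1] - sh)^2 * inv_vh + (d[2] - sv)^2 * inv_vv)
    i <- which(acc)
    if (length(i)) {
      take <- i[seq_len(min(length(i), n - got))]
      out[got + seq_along(take), ] <- cbind(sh[take], sv[take])
      got <- got + length(take)
      if (got == n) return(out)
    }
    used <- used + block
    if (used >= max_iter) {
      stop("rejection_sample_shift() exceeded its proposal cap", call. = FALSE)
    }
    block <- min(block * 2L, 65536L)
  }
}

#' Serialise / restore a learner state
#'
#' Learner snapshots are written as plain JSON with fields `m`, `kappa`,
#' `nu`, `S` (row-major), `trials_seen` and an optional `seed`, so long
#' simulations can be checkpointed and replayed.
#'
#' @param state An [niw_state()].
#' @param path File path to write to / read from.
#' @param seed Optional integer recorded alongside the state.
#' @return `write_niw_state()` returns `path` invisibly;
#'   `read_niw_state()` returns the restored `sb_niw` (the seed, if any, as
#'   attribute `"seed"`).
#' @export
write_niw_state <- function(state, path, seed = NULL) {
  stopifnot(inherits(state, "sb_niw"))
  x <- list(m = state$m, kappa = state$kappa, nu = state$nu,
            S = as.numeric(t(state$S)), trials_seen = state$trials_seen)
  if (!is.null(seed)) x$seed <- seed
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_niw_state
#' @export
read_niw_state <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- niw_state(m = x$m, kappa = x$kappa, nu = x$nu,
                  S = matrix(x$S, 2, 2, byrow = TRUE),
                  trials_seen = x$trials_seen %||% 0L)
  if (!is.null(x$seed)) attr(st, "seed") <- x$seed
  st
}
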