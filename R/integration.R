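
#' Bivariate Gaussian shift distribution
#'
#' The hidden visuomotor shift applied to the displayed hand position is a
#' bivariate Gaussian in the vertical plane, parameterised by its mean (in
#' cm; horizontal then vertical component), per-dimension standard
#' deviations and the correlation between the two dimensions. The
#' correlation is the structural invariant the experiment manipulates:
#' training on `rho = -0.999` versus `rho = 0` distinguishes the study
#' groups, while test trials always draw from the correlated distribution.
#'
#' @param mu Numeric length-2 mean in cm, default `c(-1, 1)` (the study's
#'   mean shift: 1 cm leftwards, 1 cm upwards).
#' @param sigma1,sigma2 Positive standard deviations in cm, default 1.
#' @param rho Correlation in `[-1, 1]`. Values with `|rho| = 1` make the
#'   covariance singular and are rejected by operations that need its
#'   inverse; use `|rho| <= 0.999`.
#' @return An object of class `sb_shift_dist` with elements `mu`, `sigma1`,
#'   `sigma2`, `rho` and the implied 2x2 covariance `Sigma`.
#' @examples
#' shift_distribution(rho = -0.999)
#' @export
shift_distribution <- function(mu = c(-1, 1), sigma1 = 1, sigma2 = 1, rho = 0) {
  mu <- as_len2(mu, "mu")
  stopifnot(sigma1 > 0, sigma2 > 0, rho >= -1, rho <= 1)
  Sigma <- matrix(c(sigma1^2, rho * sigma1 * sigma2,
                    rho * sigma1 * sigma2, sigma2^2), 2, 2)
  structure(list(mu = mu, sigma1 = sigma1, sigma2 = sigma2, rho = rho,
                 Sigma = Sigma),
            class = "sb_shift_dist")
}

#' @export
print.sb_shift_dist <- function(x, ...) {
  cat(sprintf("<shift distribution> mu = (%.3g, %.3g) cm, sd = (%.3g, %.3g) cm, rho = %.4g\n",
              x$mu[1], x$mu[2], x$sigma1, x$sigma2, x$rho))
  invisible(x)
}

#' Feedback conditions
#'
#' The four visual feedback reliabilities of the task: `FULL` (a precise
#' cursor, reliable in both dimensions), `PARTIAL_H` (a vertically elongated
#' bar: reliable horizontally, uninformative vertically), `PARTIAL_V` (the
#' transposed bar), and `NONE` (no visual feedback).
#'
#' @format A character vector of the four condition tags.
#' @export
FEEDBACK_CONDITIONS <- c("FULL", "PARTIAL_H", "PARTIAL_V", "NONE")

check_condition <- function(condition) {
  if (length(condition) != 1L || !condition %in% FEEDBACK_CONDITIONS) {
    stop(sprintf("unknown feedback condition tag: %s",
                 paste(condition, collapse = ", ")), call. = FALSE)
  }
  condition
}

#' Observation-noise covariance for a feedback condition
#'
#' Visual feedback is modelled through a Gaussian likelihood with diagonal
#' covariance; each diagonal entry is the feedback variance in that
#' dimension. A reliable dimension gets the profile's `low` variance, an
#' uninformative one its `high` variance; `high = Inf` represents a
#' dimension that carries no information at all (zero precision). The
#' study's profile is `low = 0.2` cm^2 and `high = 40` cm^2; the exact-limit
#' profile `high = Inf` is used for ideal-actor predictions.
#'
#' @param condition One of [FEEDBACK_CONDITIONS].
#' @param profile List with elements `low` and `high`, variances in cm^2.
#'   `high` may be `Inf`.
#' @return An `sb_obs_noise` object with fields `var_h` and `var_v` (cm^2).
#' @examples
#' condition_noise("PARTIAL_H")           # var_h = 0.2, var_v = 40
#' condition_noise("NONE", noise_profile(high = Inf))
#' @export
condition_noise <- function(condition, profile = noise_profile()) {
  check_condition(condition)
  stopifnot(is.numeric(profile$low), profile$low > 0,
            is.numeric(profile$high), profile$high > 0)
  v <- switch(condition,
    FULL      = c(profile$low,  profile$low),
    PARTIAL_H = c(profile$low,  profile$high),
    PARTIAL_V = c(profile$high, profile$low),
    NONE      = c(profile$high, profile$high))
  obs_noise(v[1], v[2])
}

#' @rdname condition_noise
#' @param low,high Variances in cm^2 for reliable / uninformative feedback
#'   dimensions.
#' @export
noise_profile <- function(low = 0.2, high = 40) {
  stopifnot(low > 0, high > 0)
  list(low = low, high = high)
}

#' @rdname condition_noise
#' @param var_h,var_v Diagonal entries of the feedback covariance, cm^2
#'   (may be `Inf`). Off-diagonals are identically zero.
#' @export
obs_noise <- function(var_h, var_v) {
  stopifnot(is.numeric(var_h), var_h > 0, is.numeric(var_v), var_v > 0)
  structure(list(var_h = var_h, var_v = var_v), class = "sb_obs_noise")
}

#' @export
print.sb_obs_noise <- function(x, ...) {
  cat(sprintf("<observation noise> diag(%g, %g) cm^2\n", x$var_h, x$var_v))
  invisible(x)
}

#' Gaussian belief over the shift
#'
#' A bivariate Gaussian belief (mean in cm, covariance in cm^2), the output
#' of [posterior_belief()] and the generic container for any Gaussian over
#' the 2-D shift.
#'
#' @param mean Numeric length-2, cm.
#' @param cov Symmetric positive semi-definite 2x2 matrix, cm^2.
#' @return An `sb_belief` object.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as_len2(mean, "mean")
  check_sym_psd(cov, "cov")
  if (det2(cov[1, 1], cov[1, 2], cov[2, 2]) < -1e-10 || cov[1, 1] < 0) {
    stop("`cov` must be positive semi-definite", call. = FALSE)
  }
  structure(list(mean = mean, cov = cov), class = "sb_belief")
}

#' @export
print.sb_belief <- function(x, ...) {
  cat(sprintf("<Gaussian belief> mean = (%.4g, %.4g) cm\n", x$mean[1], x$mean[2]))
  cat("  cov (cm^2):\n")
  print(round(x$cov, 6))
  invisible(x)
}

prior_precision <- function(prior) {
  S <- prior$Sigma
  d <- det2(S[1, 1], S[1, 2], S[2, 2])
  if (d <= 0 || abs(prior$rho) >= 1) {
    stop("prior covariance is singular (|rho| = 1); use |rho| <= 0.999 or the limit formulas",
         call. = FALSE)
  }
  iv <- inv2(S[1, 1], S[1, 2], S[2, 2])
  matrix(c(iv[1], iv[2], iv[2], iv[3]), 2, 2)
}

#' Posterior belief after seeing visual feedback
#'
#' Combines a Gaussian prior over the shift with the Gaussian feedback
#' likelihood in precision form: the posterior covariance is
#' `(Sigma^-1 + Sigma_obs^-1)^-1` and the posterior mean is
#' `Sigma_p (Sigma_obs^-1 d + Sigma^-1 mu)`. An infinite feedback variance
#' contributes zero precision, so the no-feedback condition returns the
#' prior exactly, and a partial condition ignores the feedback coordinate of
#' the uninformative dimension (its `d` entry may be `NA`).
#'
#' @param prior An [shift_distribution()] (or any object with `mu` and
#'   `Sigma`).
#' @param noise An [obs_noise()].
#' @param d Feedback point, numeric length-2 in cm. Entries of dimensions
#'   with infinite variance may be `NA`.
#' @return An [gaussian_belief()] with the posterior mean and covariance.
#' @examples
#' pr <- shift_distribution(rho = -0.999)
#' posterior_belief(pr, condition_noise("PARTIAL_H"), c(0, NA))
#' @export
posterior_belief <- function(prior, noise, d) {
  P  <- prior_precision(prior)
  ph <- if (is.finite(noise$var_h)) 1 / noise$var_h else 0
  pv <- if (is.finite(noise$var_v)) 1 / noise$var_v else 0
  d  <- as.numeric(d)
  if (length(d) != 2L) stop("`d` must have length 2", call. = FALSE)
  dh <- if (ph > 0) d[1] else 0   # zero-precision dims contribute nothing
  dv <- if (pv > 0) d[2] else 0
  if ((ph > 0 && !is.finite(dh)) || (pv > 0 && !is.finite(dv))) {
    stop("feedback `d` must be finite in every informative dimension", call. = FALSE)
  }
  Ppost <- P + diag(c(ph, pv))
  iv <- inv2(Ppost[1, 1], Ppost[1, 2], Ppost[2, 2])
  Sp <- matrix(c(iv[1], iv[2], iv[2], iv[3]), 2, 2)
  mp <- drop(Sp %*% (c(ph * dh, pv * dv) + P %*% prior$mu))
  gaussian_belief(mp, Sp)
}

#' Ideal compensatory response
#'
#' The ideal actor cancels the expected shift: its terminal hand offset is
#' minus the posterior mean, so that the displayed (shifted) position lands
#' on the target in expectation.
#'
#' @param belief An [gaussian_belief()].
#' @return Numeric length-2 response in cm (deviation coordinates).
#' @export
ideal_response <- function(belief) {
  -as_len2(belief$mean, "belief$mean")
}

#' Predicted deviation-versus-shift slope of the ideal actor
#'
#' For an actor that responds with minus the posterior mean, the terminal
#' deviation in a trial is `s - mu_p(d = s)`. Regressing the deviation in
#' one dimension on the true shift in that dimension, across trials drawn
#' from the prior, gives slope `1 - (W Sigma)_kk / Sigma_kk` where
#' `W = Sigma_p Sigma_obs^-1` is the feedback weight matrix. Slope 0 means
#' full feedback-driven compensation, slope 1 pure reliance on the prior
#' mean. With a correlated prior the uninformative dimension of a partial
#' condition picks up weight through the informative one, which is the
#' task's signature of structure learning: its slope is `1 - rho^2` in the
#' reliable-feedback limit.
#'
#' @inheritParams condition_noise
#' @param prior An [shift_distribution()] describing both the actor's belief
#'   and the generative distribution of the shifts being regressed on.
#' @return Named numeric `c(h = , v = )` slope pair (dimensionless).
#' @examples
#' ideal_slope(shift_distribution(rho = 0), "PARTIAL_H",
#'             noise_profile(low = 1, high = Inf))  # c(h = 0.5, v = 1)
#' @export
ideal_slope <- function(prior, condition, profile = noise_profile()) {
  check_condition(condition)
  noise <- condition_noise(condition, profile)
  P  <- prior_precision(prior)
  ph <- if (is.finite(noise$var_h)) 1 / noise$var_h else 0
  pv <- if (is.finite(noise$var_v)) 1 / noise$var_v else 0
  Ppost <- P + diag(c(ph, pv))
  iv <- inv2(Ppost[1, 1], Ppost[1, 2], Ppost[2, 2])
  Sp <- matrix(c(iv[1], iv[2], iv[2], iv[3]), 2, 2)
  W  <- Sp %*% diag(c(ph, pv))
  WS <- W %*% prior$Sigma
  c(h = 1 - WS[1, 1] / prior$Sigma[1, 1],
    v = 1 - WS[2, 2] / prior$Sigma[2, 2])
}
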