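
#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a robust slope fit
#'
#' @param x An `sb_slope_fit` from [robust_line()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`estimate`,
#'   `std.error` for the slope term).
#' @export
tidy.sb_slope_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(NA_real_, x$slope_se))
}

#' @rdname tidy.sb_slope_fit
#' @export
glance.sb_slope_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 slope_se = x$slope_se, n = x$n, converged = x$converged,
                 dimension = x$dimension, condition = x$condition)
}

#' Tidy an NIW belief state
#'
#' Returns the hyper-parameters together with the implied posterior-mean
#' shift distribution: `E[Theta] = S / (nu - 3)` and the prior covariance
#' after removing the subsumed full-feedback noise, with its implied
#' correlation.
#'
#' @param x An [niw_state()].
#' @param obs_noise_full FULL-condition [obs_noise()] subtracted from
#'   `E[Theta]`.
#' @param ... Unused.
#' @return One-row tibble: `m_h`, `m_v`, `kappa`, `nu`, `trials_seen`,
#'   `var_h`, `var_v`, `cov_hv`, `rho` (of the implied prior).
#' @export
tidy.sb_niw <- function(x, obs_noise_full = condition_noise("FULL"), ...) {
  ETheta <- x$S / (x$nu - 3)
  Sigma0 <- ETheta - diag(c(obs_noise_full$var_h, obs_noise_full$var_v))
  tibble::tibble(m_h = x$m[1], m_v = x$m[2], kappa = x$kappa, nu = x$nu,
                 trials_seen = x$trials_seen,
                 var_h = Sigma0[1, 1], var_v = Sigma0[2, 2],
                 cov_hv = Sigma0[1, 2],
                 rho = Sigma0[1, 2] / sqrt(Sigma0[1, 1] * Sigma0[2, 2]))
}

#' Glance at a reproduction run
#'
#' @param x An `sb_reproduction` from [reproduce_study()].
#' @param ... Unused.
#' @return The summary tibble of last-session medians in wide format.
#' @export
glance.sb_reproduction <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "statistic",
                     values_from = "last_session_median")
}
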