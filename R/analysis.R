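
#' Robust line fit (iteratively reweighted least squares, bisquare)
#'
#' Fits `y ~ x` by IRLS with Tukey bisquare weights at the conventional
#' tuning constant 4.685 and MAD/0.6745 scale, the robust fit used
#' throughout the behavioural analyses (slope of terminal deviation against
#' true shift). The fit is delegated to [MASS::rlm()]; when no point falls
#' beyond the tuning radius all weights are one and the fit coincides with
#' ordinary least squares.
#'
#' @param x,y Numeric vectors, `length >= 3`; `x` must not be constant.
#' @param dimension,condition Optional labels carried into the result.
#' @param maxit Iteration cap (default 50).
#' @param acc Convergence tolerance on the IRLS weights (default 1e-8).
#' @return An `sb_slope_fit` list: `slope`, `intercept`, `slope_se`, `n`,
#'   `converged`, plus the labels. Has [tidy()] and [glance()] methods.
#' @examples
#' f <- robust_line(1:20, 0.5 * (1:20) + 1)
#' f$slope  # 0.5
#' @export
robust_line <- function(x, y, dimension = NA_character_,
                        condition = NA_character_, maxit = 50, acc = 1e-8) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("robust_line() needs at least 3 finite points", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant; slope is undefined", call. = FALSE)
  if (stats::sd(y) == 0) {
    # exact flat data: IRLS scale is zero, the fit is the constant line
    return(structure(list(slope = 0, intercept = y[1], slope_se = 0,
                          n = length(x), converged = TRUE,
                          dimension = dimension, condition = condition),
                     class = "sb_slope_fit"))
  }
  fit <- withCallingHandlers(
    MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
              scale.est = "MAD", maxit = maxit, acc = acc),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf["x", "Value"]),
                 intercept = unname(cf["(Intercept)", "Value"]),
                 slope_se = unname(cf["x", "Std. Error"]),
                 n = length(x), converged = fit$converged,
                 dimension = dimension, condition = condition),
            class = "sb_slope_fit")
}

#' @export
print.sb_slope_fit <- function(x, ...) {
  cat(sprintf("<robust slope fit> slope = %.4g (SE %.3g), intercept = %.4g cm, n = %d%s\n",
              x$slope, x$slope_se, x$intercept, x$n,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

# records columns for a given dimension
dim_cols <- function(dimension) {
  dimension <- match.arg(dimension, c("h", "v"))
  list(s = paste0("s_", dimension), dev = paste0("dev_", dimension))
}

#' Per-condition robust slopes for one participant
#'
#' For each feedback condition present in the records, fits the robust line
#' of terminal deviation against true shift in the requested dimension.
#' Partial conditions are informative in one dimension and uninformative in
#' the other, so fitting both dimensions characterises both the direct use
#' of feedback and any structure transfer. Session-1 training-stage trials
#' are excluded.
#'
#' @param records Trial-record tibble (one participant, or one cohort if
#'   `by_participant = TRUE`).
#' @param dimension `"h"` or `"v"`.
#' @param sessions Optional sessions to keep (default: all).
#' @param by_participant Fit per participant (default `TRUE` when several
#'   participants are present).
#' @return A tibble with one row per (participant,) condition: `slope`,
#'   `intercept`, `slope_se`, `n`; conditions with fewer than 3 trials get
#'   `NA` estimates.
#' @export
condition_slopes <- function(records, dimension = c("h", "v"),
                             sessions = NULL,
                             by_participant = length(unique(records$participant)) > 1) {
  dimension <- match.arg(dimension)
  cols <- dim_cols(dimension)
  recs <- dplyr::filter(records, .data$phase == "main")
  if (!is.null(sessions)) recs <- dplyr::filter(recs, .data$session %in% !!sessions)
  grp <- if (by_participant) c("participant", "condition") else "condition"
  out <- recs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3L) {
        return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                              slope_se = NA_real_, n = nrow(df)))
      }
      f <- robust_line(df[[cols$s]], df[[cols$dev]])
      tibble::tibble(slope = f$slope, intercept = f$intercept,
                     slope_se = f$slope_se, n = f$n)
    }) |>
    dplyr::ungroup()
  out$dimension <- dimension
  out
}

#' Pooled uninformative-dimension partial-feedback records
#'
#' Pools the two partial conditions on their uninformative dimension (the
#' vertical dimension of `PARTIAL_H` trials and the horizontal dimension of
#' `PARTIAL_V` trials), returning a table with generic `s`/`dev` columns in
#' trial order — the quantity whose slope indexes structure learning.
#'
#' @param records Trial-record tibble.
#' @return Tibble with `participant`, `session`, `trial`, `condition`,
#'   `s`, `dev`.
#' @export
partial_uninformative <- function(records) {
  ph <- dplyr::filter(records, .data$condition == "PARTIAL_H", .data$phase == "main")
  pv <- dplyr::filter(records, .data$condition == "PARTIAL_V", .data$phase == "main")
  dplyr::bind_rows(
    dplyr::transmute(ph, .data$participant, .data$session, .data$trial,
                     .data$condition, s = .data$s_v, dev = .data$dev_v),
    dplyr::transmute(pv, .data$participant, .data$session, .data$trial,
                     .data$condition, s = .data$s_h, dev = .data$dev_h)
  ) |> dplyr::arrange(.data$participant, .data$trial)
}

# Pooled-slope helper: the two partial types have opposite mean shifts
# (-1 cm horizontally, +1 cm vertically), so a raw pooled regression mixes
# the within-type slope with a spurious between-type component. Centring s
# and dev per type inside the fitted window (a type fixed effect) removes
# it; the fitted slope is then the variance-weighted within-type slope.
center_by_type <- function(s, dev, type) {
  for (tt in unique(type)) {
    i <- type == tt
    s[i] <- s[i] - mean(s[i])
    dev[i] <- dev[i] - mean(dev[i])
  }
  list(s = s, dev = dev)
}

#' Sliding-window statistic over a filtered trial sequence
#'
#' Computes a statistic in contiguous windows sliding by one trial over the
#' requested subsequence of records (pooled across sessions, ordered by
#' global trial index). Windows are defined on the filtered sequence — the
#' k-th window of, say, no-feedback trials — and each window is labelled
#' with the session of its median trial. Statistics:
#' `"slope"` (robust deviation-vs-shift slope; conventional window 100),
#' `"mean_h"`/`"mean_v"` (mean compensatory response, `dev - s`, sign
#' flipped to absolute compensation so the ideal is +1 / -1 cm; window
#' 100), `"xy_corr"` (Pearson correlation of the horizontal and vertical
#' terminal hand positions, i.e. responses; conventional window 50).
#'
#' @param records Trial-record tibble for one participant.
#' @param statistic One of `"slope"`, `"mean_h"`, `"mean_v"`, `"xy_corr"`.
#' @param conditions Condition filter, e.g. `"NONE"`; for `"slope"` the
#'   special value `"PARTIAL_UNINF"` pools the partial conditions on their
#'   uninformative dimension (the default for slopes).
#' @param window Window length in (filtered) trials.
#' @param dimension For `"slope"`: which dimension to regress when not
#'   pooling (`"h"`/`"v"`).
#' @return An `sb_window_series` tibble: `center` (global trial index of
#'   the window's median trial), `session`, `value`, with attributes
#'   `statistic` and `window`. Has an [autoplot()] method.
#' @export
sliding_series <- function(records,
                           statistic = c("slope", "mean_h", "mean_v", "xy_corr"),
                           conditions = NULL, window = NULL,
                           dimension = c("v", "h")) {
  statistic <- match.arg(statistic)
  dimension <- match.arg(dimension)
  window <- window %||% if (statistic == "xy_corr") 50L else 100L
  pooled <- FALSE
  if (statistic == "slope") {
    conditions <- conditions %||% "PARTIAL_UNINF"
    if (identical(conditions, "PARTIAL_UNINF")) {
      df <- partial_uninformative(records)
      pooled <- TRUE
    } else {
      cols <- dim_cols(dimension)
      df <- records |>
        dplyr::filter(.data$condition %in% !!conditions, .data$phase == "main") |>
        dplyr::transmute(.data$participant, .data$session, .data$trial,
                         s = .data[[cols$s]], dev = .data[[cols$dev]])
    }
  } else {
    conditions <- conditions %||% "NONE"
    df <- records |>
      dplyr::filter(.data$condition %in% !!conditions, .data$phase == "main") |>
      dplyr::transmute(.data$participant, .data$session, .data$trial,
                       resp_h = .data$dev_h - .data$s_h,
                       resp_v = .data$dev_v - .data$s_v)
  }
  df <- dplyr::arrange(df, .data$trial)
  n <- nrow(df)
  if (window > n) {
    stop(sprintf("window (%d) larger than the filtered sequence (%d trials)",
                 window, n), call. = FALSE)
  }
  starts <- seq_len(n - window + 1L)
  value <- vapply(starts, function(i) {
    w <- i:(i + window - 1L)
    switch(statistic,
      slope = tryCatch({
        if (pooled) {
          ctr <- center_by_type(df$s[w], df$dev[w], df$condition[w])
          robust_line(ctr$s, ctr$dev)$slope
        } else {
          robust_line(df$s[w], df$dev[w])$slope
        }
      }, error = function(e) NA_real_),
      mean_h = mean(df$resp_h[w]),
      mean_v = mean(df$resp_v[w]),
      xy_corr = {
        if (stats::sd(df$resp_h[w]) == 0 || stats::sd(df$resp_v[w]) == 0) {
          NA_real_
        } else {
          stats::cor(df$resp_h[w], df$resp_v[w])
        }
      })
  }, numeric(1))
  mid <- starts + (window %/% 2L)
  out <- tibble::tibble(center = df$trial[pmin(mid, n)],
                        session = df$session[pmin(mid, n)],
                        value = value)
  structure(out, statistic = statistic, window = window,
            class = c("sb_window_series", class(out)))
}

#' Per-participant window series for a cohort
#'
#' Applies [sliding_series()] to every participant in a cohort table and
#' stacks the results in long format.
#'
#' @inheritParams sliding_series
#' @return A long tibble: `participant`, `center`, `session`, `value`,
#'   with `statistic`/`window` attributes.
#' @export
cohort_series <- function(records, statistic = "slope", conditions = NULL,
                          window = NULL, dimension = "v") {
  out <- records |>
    dplyr::group_split(.data$participant) |>
    purrr::map(function(df) {
      ser <- sliding_series(df, statistic, conditions, window, dimension)
      ser$participant <- df$participant[1]
      ser
    })
  res <- dplyr::bind_rows(out)
  structure(res, statistic = attr(out[[1]], "statistic"),
            window = attr(out[[1]], "window"),
            class = c("sb_window_series", class(res)))
}

#' Pointwise median series across participants
#'
#' Reduces a set of per-participant window series to their pointwise
#' median, keeping only window positions available for every participant
#' (the series is truncated to the shortest participant's support).
#'
#' @param series Long series tibble from [cohort_series()] (or a list of
#'   per-participant `sb_window_series`).
#' @return An `sb_window_series` tibble `center`, `session`, `value` where
#'   `center` is the ordinal window index shared by all participants.
#' @export
cohort_median_series <- function(series) {
  if (is.list(series) && !is.data.frame(series)) {
    series <- purrr::imap(series, function(s, i) {
      s$participant <- as.character(i); s
    })
    series <- dplyr::bind_rows(series)
  }
  if (length(unique(series$participant)) < 2L) {
    stop("cohort_median_series() needs at least 2 participants", call. = FALSE)
  }
  by_p <- dplyr::group_split(series, .data$participant)
  len <- min(vapply(by_p, nrow, integer(1)))
  vals <- vapply(by_p, function(s) s$value[seq_len(len)], numeric(len))
  ref <- by_p[[which.min(vapply(by_p, nrow, integer(1)))]]
  out <- tibble::tibble(center = seq_len(len),
                        session = ref$session[seq_len(len)],
                        value = apply(as.matrix(vals), 1, stats::median, na.rm = TRUE))
  structure(out, statistic = attr(series, "statistic"),
            window = attr(series, "window"),
            class = c("sb_window_series", class(out)))
}

#' No-feedback endpoint statistics
#'
#' Summarises the terminal hand positions of no-feedback trials: the mean
#' compensatory response per dimension (in absolute compensation
#' coordinates, so full compensation of the mean shift is +1 cm
#' horizontally and -1 cm vertically), the Pearson correlation between the
#' horizontal and vertical endpoints across trials, and its Fisher-z 95%
#' confidence interval. A learner that has internalised the correlated
#' shift distribution and samples from its belief shows a negative
#' endpoint correlation; a mean-compensating ideal actor (with or without
#' isotropic motor noise) does not.
#'
#' @param records Trial-record tibble of one participant.
#' @param sessions Optional session filter.
#' @return A one-row tibble: `mean_h`, `mean_v` (cm), `xy_corr`,
#'   `corr_lo`, `corr_hi`, `n`. Degenerate (zero-variance) endpoints flag
#'   the correlation as `NA`.
#' @export
nofeedback_endpoints <- function(records, sessions = NULL) {
  recs <- dplyr::filter(records, .data$condition == "NONE", .data$phase == "main")
  if (!is.null(sessions)) recs <- dplyr::filter(recs, .data$session %in% !!sessions)
  if (nrow(recs) < 3L) stop("need at least 3 no-feedback trials", call. = FALSE)
  rh <- recs$dev_h - recs$s_h
  rv <- recs$dev_v - recs$s_v
  n <- length(rh)
  if (stats::sd(rh) == 0 || stats::sd(rv) == 0) {
    r <- lo <- hi <- NA_real_
  } else {
    r <- stats::cor(rh, rv)
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    lo <- tanh(z - 1.96 * se); hi <- tanh(z + 1.96 * se)
  }
  tibble::tibble(mean_h = mean(rh), mean_v = mean(rv),
                 xy_corr = r, corr_lo = lo, corr_hi = hi, n = n)
}

#' Trial-by-trial carryover correlation
#'
#' Correlates the terminal deviation in no-feedback trials with the shift
#' of the immediately preceding full-feedback trial, per dimension, with a
#' permutation p-value (shuffling the previous-shift column). A
#' significant carryover indicates trial-by-trial adaptation rather than
#' (or in addition to) belief sampling.
#'
#' @param records Trial-record tibble of one participant.
#' @param n_perm Number of permutations for the p-value.
#' @param seed Optional seed for the permutation draw.
#' @return A tibble with rows `h` and `v`: `cor`, `p_perm`, `n`,
#'   `low_power` (flag, `n < 10`).
#' @export
carryover_correlation <- function(records, n_perm = 1e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  recs <- dplyr::filter(records, .data$condition == "NONE", .data$phase == "main",
                        is.finite(.data$prev_full_s_h))
  n <- nrow(recs)
  if (n < 3L) stop("need at least 3 no-feedback trials with a preceding full-feedback shift",
                   call. = FALSE)
  one <- function(dev, prev) {
    r <- stats::cor(dev, prev)
    perm <- vapply(seq_len(n_perm),
                   function(i) stats::cor(dev, prev[sample.int(n)]), numeric(1))
    p <- (1 + sum(abs(perm) >= abs(r))) / (n_perm + 1)
    c(r, p)
  }
  h <- one(recs$dev_h, recs$prev_full_s_h)
  v <- one(recs$dev_v, recs$prev_full_s_v)
  tibble::tibble(dimension = c("h", "v"),
                 cor = c(h[1], v[1]), p_perm = c(h[2], v[2]),
                 n = n, low_power = n < 10L)
}

#' Nonparametric group comparisons
#'
#' The study's hypothesis-test utilities on per-participant statistics:
#' Wilcoxon signed-rank for paired within-participant comparisons,
#' Wilcoxon rank-sum for unpaired between-group comparisons, and the
#' one-sample sign test (exact binomial) for the sign of a set of values.
#' Exact p-values are used for small samples (`n <= 25`, no ties); ties
#' fall back to the mid-rank normal approximation, which is noted in the
#' result.
#'
#' @param a Numeric vector of per-participant statistics.
#' @param b Second vector (`NULL` for the one-sample sign test).
#' @param paired Paired comparison (signed-rank) or unpaired (rank-sum).
#' @param mu Null value for the sign test.
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `n`, `exact`,
#'   `note`.
#' @examples
#' group_compare(c(-2, -1, -3, -0.5, -1.2, -0.8))  # sign test, p = 0.03125
#' @export
group_compare <- function(a, b = NULL, paired = FALSE, mu = 0) {
  a <- as.numeric(a)
  note <- NA_character_
  if (is.null(b)) {
    x <- a[a != mu]
    if (length(x) < length(a)) note <- "values equal to the null were dropped"
    if (length(x) == 0L) {
      return(tibble::tibble(test = "sign", statistic = NA_real_, p_value = NA_real_,
                            n = length(a), exact = TRUE,
                            note = "degenerate: all values at the null"))
    }
    k <- sum(x > mu)
    ht <- stats::binom.test(k, length(x), 0.5)
    return(tibble::tibble(test = "sign", statistic = as.numeric(k),
                          p_value = ht$p.value, n = length(a), exact = TRUE,
                          note = note))
  }
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per group", call. = FALSE)
  if (paired && length(a) != length(b)) stop("paired groups must have equal length", call. = FALSE)
  if (paired && all(a == b)) {
    return(tibble::tibble(test = "signed-rank", statistic = NA_real_,
                          p_value = NA_real_, n = length(a), exact = TRUE,
                          note = "degenerate: no nonzero differences"))
  }
  vals <- c(a, b)
  small <- length(a) <= 25 && length(b) <= 25
  ties <- anyDuplicated(if (paired) abs(a - b)[a != b] else vals) > 0 ||
    (paired && any(a == b))
  exact <- small && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired, exact = exact,
                                            correct = !exact))
  if (!exact) note <- "ties or large n: mid-rank normal approximation"
  tibble::tibble(test = if (paired) "signed-rank" else "rank-sum",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = length(a), exact = exact, note = note)
}

#' Full behavioural analysis of a record table
#'
#' Convenience wrapper producing the standard result bundle from any
#' trial-record table (simulated or imported): per-participant,
#' per-session condition slopes in both dimensions; the pooled
#' uninformative-dimension partial slope series (window 100); the
#' no-feedback mean-response series (window 100) and xy-correlation series
#' (window 50) with their cohort medians; per-participant, per-session
#' no-feedback endpoint statistics; and carryover correlations.
#'
#' @param records Trial-record tibble (any number of participants).
#' @param slope_window,corr_window,mean_window Window lengths.
#' @param n_perm Permutations for the carryover p-values.
#' @param seed Seed for the permutation draws.
#' @return An `sb_analysis` list of tibbles: `slopes`, `partial_slope`,
#'   `mean_h`, `mean_v`, `xy_corr` (each with `$series` per participant and
#'   `$median` across participants when possible), `endpoints`,
#'   `carryover`.
#' @export
analyze_records <- function(records, slope_window = 100L, corr_window = 50L,
                            mean_window = 100L, n_perm = 2000L, seed = 1L) {
  participants <- unique(records$participant)
  sessions <- sort(unique(records$session))
  slopes <- dplyr::bind_rows(
    purrr::map(sessions, function(ss) {
      dplyr::bind_rows(
        dplyr::mutate(condition_slopes(records, "h", sessions = ss,
                                       by_participant = TRUE), session = ss),
        dplyr::mutate(condition_slopes(records, "v", sessions = ss,
                                       by_participant = TRUE), session = ss))
    }))
  mk <- function(statistic, conditions, window) {
    ser <- tryCatch(cohort_series(records, statistic, conditions, window),
                    error = function(e) NULL)
    med <- if (!is.null(ser) && length(participants) >= 2L) {
      cohort_median_series(ser)
    }
    list(series = ser, median = med)
  }
  endpoints <- dplyr::bind_rows(purrr::map(participants, function(p) {
    dplyr::bind_rows(purrr::map(sessions, function(ss) {
      e <- tryCatch(nofeedback_endpoints(
        dplyr::filter(records, .data$participant == p), sessions = ss),
        error = function(e) NULL)
      if (!is.null(e)) dplyr::mutate(e, participant = p, session = ss)
    }))
  }))
  carry <- dplyr::bind_rows(purrr::map(participants, function(p) {
    ct <- tryCatch(
      carryover_correlation(dplyr::filter(records, .data$participant == p),
                            n_perm = n_perm, seed = seed),
      error = function(e) NULL)
    if (!is.null(ct)) dplyr::mutate(ct, participant = p)
  }))
  structure(list(
    slopes = slopes,
    partial_slope = mk("slope", "PARTIAL_UNINF", slope_window),
    mean_h = mk("mean_h", "NONE", mean_window),
    mean_v = mk("mean_v", "NONE", mean_window),
    xy_corr = mk("xy_corr", "NONE", corr_window),
    endpoints = endpoints,
    carryover = carry
  ), class = "sb_analysis")
}

#' @export
print.sb_analysis <- function(x, ...) {
  cat("<behavioural analysis bundle>\n")
  cat(sprintf("  %d condition-slope fits; window series: partial slope, mean_h, mean_v, xy_corr\n",
              nrow(x$slopes)))
  cat(sprintf("  %d endpoint summaries, %d carryover rows\n",
              nrow(x$endpoints), nrow(x$carryover)))
  invisible(x)
}

# last-session median of a cohort median series (helper used by the
# reproduction driver and the acceptance checks)
last_session_median <- function(median_series) {
  if (is.null(median_series)) return(NA_real_)
  last <- max(median_series$session)
  stats::median(median_series$value[median_series$session == last], na.rm = TRUE)
}
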