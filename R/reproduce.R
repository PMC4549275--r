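
#' Reproduce the study's simulation results
#'
#' The end-to-end driver: simulates a cohort of virtual sampling-learner
#' participants for each requested group under one configuration, runs the
#' full behavioural analysis on each cohort, and collects the figure-level
#' summaries — the cohort-median uninformative-dimension partial-feedback
#' slope series, no-feedback mean-response series, and no-feedback
#' xy-correlation series, together with their last-session medians. If an
#' imported human data table is supplied its statistics are computed side
#' by side with the simulation's.
#'
#' @param config An [run_config()].
#' @param human Optional trial-record tibble of imported human data.
#' @param out_dir Optional directory; when given, per-group record CSVs,
#'   long-format series CSVs and a JSON manifest (seeds, configuration,
#'   versions, runtimes) are written there.
#' @return An `sb_reproduction` list: `records` (named by group),
#'   `analysis` (named by group), `summary` (tibble of last-session
#'   medians per group and statistic), `human` (analysis of the imported
#'   data or `NULL`), `config`, `manifest`.
#' @examples
#' \donttest{
#' rep <- reproduce_study(run_config(seed = 17, n_participants = 2,
#'                                   sessions = 2, trials_per_session = 300))
#' rep$summary
#' }
#' @export
reproduce_study <- function(config = run_config(), human = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(config, "sb_run_config"))
  t0 <- Sys.time()
  actor <- actor_from_config(config)
  records <- list(); analysis <- list(); summaries <- list()
  for (g in config$groups) {
    grp <- group_config(g)
    recs <- simulate_cohort(grp, actor, config$n_participants, config$seed,
                            config$sessions, config$trials_per_session)
    an <- analyze_records(recs, slope_window = config$slope_window,
                          corr_window = config$corr_window,
                          mean_window = config$mean_window,
                          seed = config$seed)
    records[[g]] <- recs
    analysis[[g]] <- an
    summaries[[g]] <- tibble::tibble(
      group = g,
      statistic = c("partial_slope", "mean_h", "mean_v", "xy_corr"),
      last_session_median = c(
        last_session_median(an$partial_slope$median %||% one_series(an$partial_slope$series)),
        last_session_median(an$mean_h$median %||% one_series(an$mean_h$series)),
        last_session_median(an$mean_v$median %||% one_series(an$mean_v$series)),
        last_session_median(an$xy_corr$median %||% one_series(an$xy_corr$series))
      ))
  }
  human_an <- if (!is.null(human)) {
    analyze_records(human, slope_window = config$slope_window,
                    corr_window = config$corr_window,
                    mean_window = config$mean_window, seed = config$seed)
  }
  manifest <- list(
    seed = config$seed,
    participant_seeds = lapply(stats::setNames(config$groups, config$groups),
                               function(g) vapply(seq_len(config$n_participants),
                                                  function(i) participant_seed(config$seed, i),
                                                  integer(1))),
    config = unclass(config),
    package_version = as.character(utils::packageVersion("structbayes")),
    r_version = R.version.string,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out <- structure(list(records = records, analysis = analysis,
                        summary = dplyr::bind_rows(summaries),
                        human = human_an, config = config,
                        manifest = manifest),
                   class = "sb_reproduction")
  if (!is.null(out_dir)) write_reproduction(out, out_dir)
  out
}

one_series <- function(series) {
  # single-participant fallback: treat the lone series as the "median"
  if (is.null(series)) return(NULL)
  series
}

write_reproduction <- function(rep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(rep$records)) {
    write_trial_records(rep$records[[g]],
                        file.path(out_dir, paste0("records_", g, ".csv")))
    long <- purrr::imap(
      rep$analysis[[g]][c("partial_slope", "mean_h", "mean_v", "xy_corr")],
      function(x, nm) {
        if (is.null(x$series)) return(NULL)
        dplyr::mutate(tibble::as_tibble(x$series), statistic = nm)
      }) |> dplyr::bind_rows()
    readr::write_csv(long, file.path(out_dir, paste0("series_", g, ".csv")))
  }
  readr::write_csv(rep$summary, file.path(out_dir, "summary.csv"))
  jsonlite::write_json(rep$manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.sb_reproduction <- function(x, ...) {
  cat("<reproduction run>\n")
  cat(sprintf("  groups: %s; %d participants x %d sessions x %d trials; seed %d\n",
              paste(x$config$groups, collapse = ", "), x$config$n_participants,
              x$config$sessions, x$config$trials_per_session, x$config$seed))
  print(x$summary)
  invisible(x)
}

#' Grid search over the initial-belief weights
#'
#' Fits the learner's initial pseudo-count weights `(kappa0, nu0)` — which
#' govern the learning rates of the mean and of the covariance — by
#' simulated matching: for every grid cell, cohorts of virtual
#' participants are simulated and the medians of the five behavioural
#' series (uninformative-dimension partial slopes in the horizontal and
#' vertical dimension, no-feedback mean responses in both dimensions, and
#' the no-feedback xy-correlation) are compared to the supplied target
#' series by summed squared error on a common support (series are
#' truncated/interpolated to the shorter one). Cell seeds are a fixed hash
#' of the top-level seed and the cell coordinates, so the SSE surface is
#' independent of evaluation order.
#'
#' @param targets Named list of target series (tibbles with `center` and
#'   `value`), any subset of `slope_h`, `slope_v`, `mean_h`, `mean_v`,
#'   `xy_corr`.
#' @param kappa0_grid,nu0_grid Numeric grids of candidate weights.
#' @param runs Virtual participants per cell (the study fitted with 30
#'   runs).
#' @param seed Top-level seed.
#' @param group Training group simulated against the targets.
#' @param sessions,trials_per_session Study size per run.
#' @param windows Named window lengths (`slope`, `mean`, `corr`).
#' @return A list: `best` (tibble row with `kappa0`, `nu0`, `sse`) and
#'   `surface` (tibble with one row per cell).
#' @export
grid_search_fit <- function(targets, kappa0_grid, nu0_grid, runs = 6L,
                            seed = 1L, group = "correlated",
                            sessions = 4L, trials_per_session = 1000L,
                            windows = c(slope = 100L, mean = 100L, corr = 50L)) {
  if (!length(kappa0_grid) || !length(nu0_grid)) {
    stop("empty parameter grid", call. = FALSE)
  }
  stopifnot(is.list(targets), length(targets) > 0)
  grp <- group_config(group)
  cells <- expand.grid(kappa0 = kappa0_grid, nu0 = nu0_grid)
  sse <- vapply(seq_len(nrow(cells)), function(ci) {
    k0 <- cells$kappa0[ci]; n0 <- cells$nu0[ci]
    # cell seed depends on the cell's parameters, not its position in the
    # grid, so the surface is invariant to evaluation order
    cell_seed <- participant_seed(seed,
                                  (round(1e3 * log1p(k0)) * 131 +
                                     round(1e3 * log1p(n0))) %% 1e6)
    actor <- actor_config(state = niw_state(kappa = k0, nu = n0, S = diag(n0, 2)))
    recs <- simulate_cohort(grp, actor, runs, cell_seed, sessions,
                            trials_per_session)
    med <- simulated_medians(recs, windows)
    sum(vapply(names(targets), function(nm) {
      if (is.null(med[[nm]])) return(0)
      series_sse(targets[[nm]], med[[nm]])
    }, numeric(1)))
  }, numeric(1))
  surface <- tibble::as_tibble(cells)
  surface$sse <- sse
  list(best = surface[which.min(surface$sse), ], surface = surface)
}

# cohort-median series of the five fitted quantities
simulated_medians <- function(recs, windows = c(slope = 100L, mean = 100L,
                                                corr = 50L)) {
  med <- function(statistic, conditions, window, dimension = "v") {
    tryCatch({
      ser <- cohort_series(recs, statistic, conditions, window, dimension)
      if (length(unique(ser$participant)) >= 2L) cohort_median_series(ser) else ser
    }, error = function(e) NULL)
  }
  list(
    slope_h = med("slope", "PARTIAL_V", windows[["slope"]], dimension = "h"),
    slope_v = med("slope", "PARTIAL_H", windows[["slope"]], dimension = "v"),
    mean_h = med("mean_h", "NONE", windows[["mean"]]),
    mean_v = med("mean_v", "NONE", windows[["mean"]]),
    xy_corr = med("xy_corr", "NONE", windows[["corr"]])
  )
}

# SSE between two series on the shorter common support (by window index)
series_sse <- function(target, simulated) {
  if (is.null(target) || is.null(simulated)) return(0)
  n <- min(nrow(target), nrow(simulated))
  if (n == 0L) return(0)
  tv <- target$value; sv <- simulated$value
  if (nrow(target) != nrow(simulated)) {
    # interpolate the longer series onto the shorter support
    if (nrow(target) > n) tv <- stats::approx(seq_along(tv), tv, n = n)$y
    if (nrow(simulated) > n) sv <- stats::approx(seq_along(sv), sv, n = n)$y
  }
  sum((tv[seq_len(n)] - sv[seq_len(n)])^2, na.rm = TRUE)
}
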