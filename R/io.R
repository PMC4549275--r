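
record_columns <- c("participant", "group", "session", "trial", "phase",
                    "condition", "s_h", "s_v", "d_h", "d_v", "dev_h", "dev_v",
                    "hit", "prev_full_s_h", "prev_full_s_v")

record_col_types <- readr::cols(
  participant = readr::col_character(), group = readr::col_character(),
  session = readr::col_integer(), trial = readr::col_integer(),
  phase = readr::col_character(), condition = readr::col_character(),
  s_h = readr::col_double(), s_v = readr::col_double(),
  d_h = readr::col_double(), d_v = readr::col_double(),
  dev_h = readr::col_double(), dev_v = readr::col_double(),
  hit = readr::col_logical(),
  prev_full_s_h = readr::col_double(), prev_full_s_v = readr::col_double()
)

#' Write / read trial-record tables
#'
#' Trial records travel as plain comma-separated text in the canonical
#' dialect (UTF-8, "." decimal, mandatory header, empty fields for missing
#' values) with the fixed column set
#' `participant, group, session, trial, phase, condition, s_h, s_v, d_h,
#' d_v, dev_h, dev_v, hit, prev_full_s_h, prev_full_s_v`
#' (positions in cm, `hit` logical). An optional JSON sidecar
#' (`<path>.meta.json`) records seeds, configuration and package version.
#'
#' @param records Trial-record tibble.
#' @param path CSV file path.
#' @param meta Optional named list written to the sidecar.
#' @return `write_trial_records()` returns `path` invisibly;
#'   `read_trial_records()` the tibble (sidecar, if present, as attribute
#'   `"meta"`).
#' @export
write_trial_records <- function(records, path, meta = NULL) {
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols)) {
    stop("records are missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(records[record_columns], path, na = "")
  if (!is.null(meta)) {
    meta$package_version <- as.character(utils::packageVersion("structbayes"))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_trial_records
#' @export
read_trial_records <- function(path) {
  out <- readr::read_csv(path, col_types = record_col_types, na = "")
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) {
    attr(out, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  out
}

#' Column mapping for importing foreign per-trial tables
#'
#' Describes how a deposited per-trial table maps onto the canonical
#' record columns: a named character vector `columns` maps canonical names
#' to foreign column names; `scale` gives multiplicative unit factors for
#' the position columns (e.g. `0.1` for millimetre data); dictionaries
#' translate foreign condition and group labels. Mandatory canonical
#' fields are `participant`, `session`, `trial`, `condition`, `s_h`,
#' `s_v`, `dev_h`, `dev_v`; everything else is derived or left absent.
#'
#' @param columns Named character vector, canonical -> foreign names.
#' @param scale Named numeric vector of unit scale factors for position
#'   columns (default 1, i.e. data already in cm).
#' @param condition_labels Named character vector, foreign -> canonical
#'   condition tags.
#' @param group_labels Named character vector, foreign -> canonical group
#'   names.
#' @return An `sb_import_mapping` list.
#' @export
import_mapping <- function(columns, scale = NULL,
                           condition_labels = NULL, group_labels = NULL) {
  mandatory <- c("participant", "session", "trial", "condition",
                 "s_h", "s_v", "dev_h", "dev_v")
  missing_cols <- setdiff(mandatory, names(columns))
  if (length(missing_cols)) {
    stop("mapping is missing mandatory fields: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  structure(list(columns = columns, scale = scale,
                 condition_labels = condition_labels,
                 group_labels = group_labels),
            class = "sb_import_mapping")
}

identity_mapping <- function() {
  import_mapping(stats::setNames(record_columns, record_columns))
}

#' Import a foreign per-trial table
#'
#' Reads a delimited per-trial table and normalises it to the canonical
#' record layout through an [import_mapping()]: columns are renamed,
#' position columns rescaled to cm, condition and group labels translated,
#' and `prev_full_s_h`/`prev_full_s_v` derived by scanning each
#' participant's trial order when not supplied. Values outside +-20 cm
#' after scaling trigger a unit-mismatch warning.
#'
#' @param path Delimited text file (or a tibble already in memory).
#' @param mapping An [import_mapping()]; default expects the canonical
#'   layout.
#' @return Trial-record tibble; per-group participant counts are attached
#'   as attribute `"participants_per_group"`.
#' @export
import_trials <- function(path, mapping = identity_mapping()) {
  stopifnot(inherits(mapping, "sb_import_mapping"))
  raw <- if (is.data.frame(path)) tibble::as_tibble(path) else {
    readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  }
  cm <- mapping$columns
  missing_cols <- setdiff(unname(cm), names(raw))
  if (length(missing_cols)) {
    stop("imported table is missing mapped columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in record_columns) {
    out[[canon]] <- if (canon %in% names(cm)) raw[[cm[[canon]]]] else NA
  }
  pos_cols <- c("s_h", "s_v", "d_h", "d_v", "dev_h", "dev_v",
                "prev_full_s_h", "prev_full_s_v")
  for (col in pos_cols) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
    if (!is.null(mapping$scale) && col %in% names(mapping$scale)) {
      out[[col]] <- out[[col]] * mapping$scale[[col]]
    }
  }
  if (!is.null(mapping$condition_labels)) {
    out$condition <- unname(mapping$condition_labels[as.character(out$condition)])
  }
  if (!is.null(mapping$group_labels) && !all(is.na(out$group))) {
    out$group <- unname(mapping$group_labels[as.character(out$group)])
  }
  bad <- setdiff(unique(out$condition), FEEDBACK_CONDITIONS)
  if (length(bad)) {
    stop("unknown condition labels after mapping: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rng <- range(abs(unlist(out[c("s_h", "s_v", "dev_h", "dev_v")])), na.rm = TRUE)
  if (rng[2] > 20) {
    warning("position values exceed +-20 cm after scaling; check the unit scale factors",
            call. = FALSE)
  }
  out$participant <- as.character(out$participant)
  out$session <- as.integer(out$session)
  out$trial <- as.integer(out$trial)
  if (all(is.na(out$phase))) out$phase <- "main"
  if (all(is.na(out$hit))) {
    ok <- is.finite(out$dev_h) & is.finite(out$dev_v)
    out$hit <- NA
    out$hit[ok] <- hit_test(cbind(out$dev_h[ok], out$dev_v[ok]))
  }
  out$hit <- as.logical(out$hit)
  if (all(is.na(out$prev_full_s_h))) out <- derive_prev_full(out)
  counts <- out |>
    dplyr::distinct(.data$group, .data$participant) |>
    dplyr::count(.data$group, name = "participants")
  attr(out, "participants_per_group") <- counts
  out
}

# scan each participant's trial order and fill in the shift of the most
# recent preceding full-feedback trial
derive_prev_full <- function(records) {
  records |>
    dplyr::arrange(.data$participant, .data$trial) |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(
      .last_full = dplyr::lag(cummax(ifelse(.data$condition == "FULL",
                                            dplyr::row_number(), 0L)),
                              default = 0L),
      prev_full_s_h = ifelse(.data$.last_full > 0, .data$s_h[pmax(.data$.last_full, 1L)], NA_real_),
      prev_full_s_v = ifelse(.data$.last_full > 0, .data$s_v[pmax(.data$.last_full, 1L)], NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".last_full")
}

#' Run configuration
#'
#' Serialisable bundle of everything that defines a simulation +
#' analysis run: group names, cohort size, seed, actor parameters
#' (`m0`, `kappa0`, `nu0`, `S0` diagonal, noise profile) and analysis
#' window lengths. Defaults are the study's values. Round-trips through
#' YAML unchanged.
#'
#' @param groups Character vector of group names.
#' @param n_participants Cohort size per group.
#' @param seed Top-level seed.
#' @param m0,kappa0,nu0 Initial NIW location and pseudo-counts.
#' @param S0_diag Diagonal of the initial scale matrix (default
#'   `c(nu0, nu0)`).
#' @param noise_low,noise_high Actor noise profile, cm^2.
#' @param sessions,trials_per_session Study size.
#' @param slope_window,corr_window,mean_window Analysis windows.
#' @return An `sb_run_config` list.
#' @export
run_config <- function(groups = c("correlated", "uncorrelated"),
                       n_participants = 6L, seed = 1L,
                       m0 = c(0, 0), kappa0 = 300, nu0 = 3000,
                       S0_diag = c(nu0, nu0),
                       noise_low = 0.2, noise_high = 40,
                       sessions = 4L, trials_per_session = 1000L,
                       slope_window = 100L, corr_window = 50L,
                       mean_window = 100L) {
  structure(list(groups = groups, n_participants = as.integer(n_participants),
                 seed = as.integer(seed), m0 = m0, kappa0 = kappa0, nu0 = nu0,
                 S0_diag = S0_diag, noise_low = noise_low,
                 noise_high = noise_high, sessions = as.integer(sessions),
                 trials_per_session = as.integer(trials_per_session),
                 slope_window = as.integer(slope_window),
                 corr_window = as.integer(corr_window),
                 mean_window = as.integer(mean_window)),
            class = "sb_run_config")
}

#' @rdname run_config
#' @param config An `sb_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "sb_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

actor_from_config <- function(config) {
  actor_config(
    state = niw_state(m = config$m0, kappa = config$kappa0, nu = config$nu0,
                      S = diag(config$S0_diag)),
    profile = noise_profile(low = config$noise_low, high = config$noise_high)
  )
}
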