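#' Parcel-level BOLD time series
#'
#' The basic imaging container: one subject-session matrix of BOLD values with
#' frames as rows and parcels as columns, plus the repetition time and a
#' per-frame censoring mask (`TRUE` = usable frame). Censored frames are kept
#' in place so that transitions across scrubbed gaps can be excluded
#' downstream rather than silently joined.
#'
#' @param values Numeric matrix, frames x parcels.
#' @param tr_seconds Repetition time in seconds (sampling interval).
#' @param censor_mask Logical vector, one entry per frame; `TRUE` = usable.
#' @param subject_id,session_id Identifiers carried through the pipeline.
#' @param parcel_ids Character vector of unique parcel labels; defaults to
#'   `p1..pP`.
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(values, tr_seconds = 2, censor_mask = NULL,
                      subject_id = NA_character_, session_id = NA_character_,
                      parcel_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n_frames <- nrow(values)
  censor_mask <- censor_mask %||% rep(TRUE, n_frames)
  parcel_ids <- parcel_ids %||% paste0("p", seq_len(ncol(values)))
  if (length(censor_mask) != n_frames) {
    stop("`censor_mask` length must equal the number of frames.", call. = FALSE)
  }
  if (anyDuplicated(parcel_ids)) {
    stop("`parcel_ids` must be unique.", call. = FALSE)
  }
  if (length(parcel_ids) != ncol(values)) {
    stop("`parcel_ids` length must equal the number of parcels.", call. = FALSE)
  }
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop("`tr_seconds` must be a positive number.", call. = FALSE)
  }
  bad <- which(!is.finite(values[censor_mask, , drop = FALSE]), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rows <- which(censor_mask)[bad[1, "row"]]
    stop(sprintf(
      "non-finite value in usable frame %d, parcel %d.", rows, bad[1, "col"]
    ), call. = FALSE)
  }
  colnames(values) <- parcel_ids
  structure(
    list(
      values = values, tr_seconds = tr_seconds, censor_mask = censor_mask,
      subject_id = subject_id, session_id = session_id, parcel_ids = parcel_ids
    ),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf(
    "<parcel_ts> %s/%s: %d frames x %d parcels, TR = %gs, %d censored\n",
    x$subject_id, x$session_id, nrow(x$values), ncol(x$values),
    x$tr_seconds, sum(!x$censor_mask)
  ))
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$values)

#' Write / read a parcel time series as tab-separated text
#'
#' Frames are rows, the header row holds parcel IDs. Censored frames are
#' written as all-`NA` rows and recovered as censored on read, so the
#' writer/reader pair round-trips both values and mask exactly (doubles are
#' serialized with full round-trip precision).
#'
#' @param x A [parcel_ts].
#' @param path File path.
#' @return `write_timeseries()` returns `path` invisibly; `read_timeseries()`
#'   returns a [parcel_ts].
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "parcel_ts"))
  vals <- x$values
  vals[!x$censor_mask, ] <- NA_real_
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  body <- matrix(sprintf("%.17g", vals), nrow(vals), ncol(vals))
  body[is.na(vals)] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(x$parcel_ids, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @param tr_seconds Repetition time to attach (not stored in the TSV).
#' @param subject_id,session_id Identifiers to attach.
#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, tr_seconds = 2,
                            subject_id = NA_character_,
                            session_id = NA_character_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character(0)
  )
  if (nrow(raw) == 0) stop(sprintf("empty time-series file: %s", path), call. = FALSE)
  # strtod-based conversion: correctly rounded, so 17-digit text round-trips
  # bit-exactly (readr's fast double path is off by ULPs)
  chr <- as.matrix(raw)
  vals <- suppressWarnings(matrix(as.numeric(chr), nrow(chr), ncol(chr)))
  bad <- which(is.na(vals) & !is.nan(vals) & !(chr %in% c("NA", "")),
    arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "parse error in %s at line %d, column %d: expected a double, got '%s'.",
      path, bad[1, "row"] + 1L, bad[1, "col"], chr[bad[1, "row"], bad[1, "col"]]
    ), call. = FALSE)
  }
  censor <- !apply(vals, 1, function(r) all(is.na(r)))
  nan_bad <- which(is.nan(vals) & censor, arr.ind = TRUE)
  if (nrow(nan_bad) > 0) {
    stop(sprintf(
      "NaN in usable frame: %s row %d, column %d.",
      path, nan_bad[1, 1], nan_bad[1, 2]
    ), call. = FALSE)
  }
  parcel_ts(vals,
    tr_seconds = tr_seconds, censor_mask = censor,
    subject_id = subject_id, session_id = session_id,
    parcel_ids = colnames(raw)
  )
}

#' Seed definition
#'
#' A named set of parcel indices defining the seed system whose activity
#' drives frame selection — typically the fronto-parietal network (FPN) or
#' dorsal attention network (DAN) parcels of a functional atlas.
#'
#' @param name Seed name, e.g. `"FPN"` or `"DAN"`.
#' @param parcel_indices Integer indices into the parcel ordering (1-based).
#' @return An object of class `seed_definition`.
#' @export
seed_definition <- function(name, parcel_indices) {
  parcel_indices <- as.integer(parcel_indices)
  if (length(parcel_indices) == 0) stop("seed must contain at least one parcel.", call. = FALSE)
  if (any(parcel_indices < 1) || anyDuplicated(parcel_indices)) {
    stop("seed parcel indices must be unique positive integers.", call. = FALSE)
  }
  structure(list(name = name, parcel_indices = sort(parcel_indices)),
    class = "seed_definition"
  )
}

#' Load a cohort manifest
#'
#' The manifest is a CSV with columns `subject`, `session`, `group`, `path`
#' (one row per subject-session time-series file). Longitudinal completeness
#' is checked: subjects lacking either the pre- or post-surgical session are
#' flagged, since session differences (delta values) are undefined for them.
#'
#' @param path CSV path.
#' @param sessions Session labels expected for a complete subject.
#' @return A tibble with one row per subject-session plus a per-subject
#'   `complete` column.
#' @export
load_manifest <- function(path, sessions = c("pre", "post3m")) {
  man <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("subject", "session", "group", "path")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0) {
    stop(sprintf("manifest is missing required columns: %s.",
      paste(missing, collapse = ", ")), call. = FALSE)
  }
  man <- dplyr::group_by(man, .data$subject)
  man <- dplyr::mutate(man, complete = all(sessions %in% .data$session))
  dplyr::ungroup(man)
}

#' Load a behavioral score table
#'
#' CSV with columns `subject`, `timepoint`, `score`, `value`, `cutoff`,
#' `orientation`. `orientation` is `"higher_worse"` (timed tests such as the
#' TMT) or `"higher_better"` (accuracy tests such as the attentional
#' matrices); it determines which side of the clinical cutoff is impaired.
#'
#' @param path CSV path.
#' @return A behavior tibble.
#' @export
load_behavior <- function(path) {
  beh <- readr::read_csv(path,
    col_types = readr::cols(
      subject = readr::col_character(),
      timepoint = readr::col_character(),
      score = readr::col_character(),
      value = readr::col_double(),
      cutoff = readr::col_double(),
      orientation = readr::col_character()
    ),
    progress = FALSE
  )
  required <- c("subject", "timepoint", "score", "value", "cutoff", "orientation")
  missing <- setdiff(required, names(beh))
  if (length(missing) > 0) {
    stop(sprintf("behavior table is missing required columns: %s.",
      paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_or <- setdiff(unique(beh$orientation), c("higher_worse", "higher_better"))
  if (length(bad_or) > 0) {
    stop(sprintf("unknown orientation value(s): %s.", paste(bad_or, collapse = ", ")),
      call. = FALSE)
  }
  dup <- dplyr::count(beh, .data$subject, .data$timepoint, .data$score)
  if (any(dup$n > 1)) {
    stop("behavior table has duplicated subject-timepoint-score rows.", call. = FALSE)
  }
  beh
}

#' Load and validate a run configuration
#'
#' YAML file with pipeline settings. Unknown keys are rejected (they are
#' almost always typos); missing keys are filled from documented defaults and
#' the fully resolved configuration is returned.
#'
#' @param path YAML path, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s.", paste(unknown, collapse = ", ")),
      call. = FALSE)
  }
  unknown2 <- setdiff(names(overrides), names(defaults))
  if (length(unknown2) > 0) {
    stop(sprintf("unknown config override(s): %s.", paste(unknown2, collapse = ", ")),
      call. = FALSE)
  }
  cfg <- utils::modifyList(utils::modifyList(defaults, user), overrides)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

default_config <- function() {
  list(
    rng_seed = 1L,
    k_fixed = NULL,           # NULL = select k by consensus
    k_range = 2:8,
    n_resamples = 100L,
    subsample_fraction = 0.8,
    consensus_restarts = 1L,
    kmeans_restarts = 20L,
    selection_mode = "top_fraction",
    selection_fraction = 0.15,
    selection_z_cut = 1.0,
    polarity = "activation",
    n_perm = 1000L,
    n_boot = 500L,
    models = 1:5,
    fpn_state = NULL          # NULL = use the highest-numbered CAP state
  )
}

validate_config <- function(cfg) {
  if (!is.null(cfg$k_fixed) && (cfg$k_fixed < 1)) {
    stop("`k_fixed` must be a positive integer.", call. = FALSE)
  }
  if (any(cfg$k_range < 2)) stop("`k_range` must contain orders >= 2.", call. = FALSE)
  if (cfg$n_resamples < 2) stop("`n_resamples` must be >= 2.", call. = FALSE)
  if (cfg$subsample_fraction <= 0 || cfg$subsample_fraction > 1) {
    stop("`subsample_fraction` must be in (0, 1].", call. = FALSE)
  }
  if (!cfg$selection_mode %in% c("top_fraction", "z_threshold")) {
    stop("`selection_mode` must be 'top_fraction' or 'z_threshold'.", call. = FALSE)
  }
  if (cfg$selection_fraction <= 0 || cfg$selection_fraction > 1) {
    stop("`selection_fraction` must be in (0, 1].", call. = FALSE)
  }
  if (!cfg$polarity %in% c("activation", "both")) {
    stop("`polarity` must be 'activation' or 'both'.", call. = FALSE)
  }
  if (cfg$n_perm < 0 || cfg$n_boot < 0) stop("`n_perm`/`n_boot` must be >= 0.", call. = FALSE)
  invisible(cfg)
}
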