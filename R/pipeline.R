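#' Run the full dynamic-connectivity pipeline
#'
#' Wires all stages end to end on a synthetic cohort: simulate, z-score and
#' select frames, extract CAPs (consensus model order unless fixed), assign
#' state sequences, compute temporal metrics and longitudinal deltas,
#' classify the 1-week deficit, run the grouped behavioral PLSC on the
#' metric/score changes, and fit the outcome model suite. All artifacts are
#' written under `outdir` in the documented plain-text formats together with
#' a provenance manifest (config echo, seeds, package version, file
#' hashes). Reruns with an identical config are bit-identical.
#'
#' @param config A `run_config` from [load_config()] (or a named list of
#'   overrides passed to it).
#' @param outdir Output directory.
#' @param spec Cohort specification; default [cohort_spec()] with the
#'   config's seed.
#' @return A list of class `cap_run` with every stage result, invisibly
#'   written under `outdir`.
#' @export
run_pipeline <- function(config = load_config(), outdir = tempfile("cap_run_"),
                         spec = NULL) {
  if (!inherits(config, "run_config")) config <- load_config(overrides = config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- spec %||% cohort_spec(seed = config$rng_seed)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      writeLines(sprintf("failed at stage: %s", name),
        file.path(outdir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
        conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("simulate", generate_cohort(spec))
  seed_def <- seed_definition("FPN", spec$seed_parcels)
  policy <- frame_policy(
    mode = config$selection_mode, fraction = config$selection_fraction,
    z_cut = config$selection_z_cut, polarity = config$polarity
  )
  extraction <- stage("extract-caps", extract_caps(
    cohort$timeseries, seed_def, policy,
    k = config$k_fixed, k_range = config$k_range,
    n_resamples = config$n_resamples,
    subsample_fraction = config$subsample_fraction,
    consensus_restarts = config$consensus_restarts,
    n_restarts = config$kmeans_restarts,
    rng_seed = derive_seed(config$rng_seed, "extraction")
  ))
  k <- extraction$caps$k
  fpn_state <- config$fpn_state %||% k
  metrics <- stage("metrics", cohort_metrics(extraction$sequences,
    tr_seconds = spec$tr_seconds, k = k))
  deltas <- stage("metrics", longitudinal_delta(metrics))
  flags <- stage("classify", classify_deficit(cohort$behavior, "1w"))

  plsc <- stage("plsc", {
    brain <- deltas |>
      dplyr::filter(.data$state == fpn_state) |>
      tidyr::pivot_wider(names_from = "metric", values_from = "delta",
        id_cols = "subject")
    behav <- delta_scores(cohort$behavior) |>
      tidyr::pivot_wider(names_from = "score", values_from = "delta",
        id_cols = "subject")
    stopifnot(identical(brain$subject, behav$subject))
    groups <- ifelse(flags$deficit[match(brain$subject, flags$subject)],
      "deficit", "no_deficit")
    X <- as.matrix(dplyr::select(brain, -"subject"))
    # metrics that are constant within a group (e.g. betweenness identically
    # zero on sparsely labeled sequences) carry no association and would make
    # the within-group z-score undefined; drop them with a notice
    degen <- vapply(colnames(X), function(cn) {
      any(tapply(X[, cn], groups, stats::sd) == 0)
    }, logical(1))
    if (any(degen)) {
      warning(sprintf("dropping degenerate brain metric(s) from PLSC: %s",
        paste(colnames(X)[degen], collapse = ", ")), call. = FALSE)
      X <- X[, !degen, drop = FALSE]
    }
    fit <- plsc_fit(X, dplyr::select(behav, -"subject"), groups)
    perm <- plsc_permutation(fit, n_perm = config$n_perm,
      rng_seed = derive_seed(config$rng_seed, "perm"))
    boot <- plsc_bootstrap(fit, n_boot = config$n_boot,
      rng_seed = derive_seed(config$rng_seed, "boot"))
    list(fit = fit, permutation = perm, bootstrap = boot)
  })
  suite <- stage("predict", run_model_suite(metrics, cohort$behavior,
    fpn_state, models = config$models))

  stage("report", {
    write_cohort(cohort, file.path(outdir, "cohort"))
    readr::write_tsv(tibble::as_tibble(extraction$caps$maps,
      .name_repair = "minimal"), file.path(outdir, "cap_maps.tsv"),
      progress = FALSE)
    seq_long <- extraction$sequences |>
      dplyr::mutate(frame_label = purrr::map(.data$sequence, function(s) {
        tibble::tibble(frame = seq_along(s), label = s)
      })) |>
      dplyr::select("subject", "session", "frame_label") |>
      tidyr::unnest("frame_label")
    readr::write_csv(seq_long, file.path(outdir, "state_sequences.csv"),
      progress = FALSE)
    readr::write_csv(metrics, file.path(outdir, "metrics.csv"), progress = FALSE)
    readr::write_csv(deltas, file.path(outdir, "metric_deltas.csv"), progress = FALSE)
    readr::write_csv(flags, file.path(outdir, "deficit_flags.csv"), progress = FALSE)
    if (!is.null(extraction$consensus)) {
      jsonlite::write_json(
        list(summary = extraction$consensus$summary,
          selected_k = extraction$consensus$selected_k,
          n_resamples = extraction$consensus$n_resamples,
          subsample_fraction = extraction$consensus$subsample_fraction),
        file.path(outdir, "consensus.json"), auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(
      list(
        singular_values = plsc$fit$singular_values,
        brain_saliences = plsc$fit$brain_saliences,
        behavior_saliences = plsc$fit$behavior_saliences,
        permutation = plsc$permutation,
        bootstrap = plsc$bootstrap
      ),
      file.path(outdir, "plsc.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(suite$significance, file.path(outdir, "model_coefficients.csv"),
      progress = FALSE)
    readr::write_csv(suite$scatter_data, file.path(outdir, "scatter_data.csv"),
      progress = FALSE)
    files <- sort(setdiff(list.files(outdir, recursive = TRUE),
      "provenance.json"))
    jsonlite::write_json(
      list(
        package_version = as.character(utils::packageVersion("capdyn")),
        rng_seed = config$rng_seed,
        config = unclass(config),
        selected_k = k,
        fpn_state = fpn_state,
        file_hashes = as.list(stats::setNames(
          unname(tools::md5sum(file.path(outdir, files))), files))
      ),
      file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  })

  invisible(structure(
    list(cohort = cohort, extraction = extraction, metrics = metrics,
      deltas = deltas, flags = flags, plsc = plsc, suite = suite,
      config = config, outdir = outdir),
    class = "cap_run"
  ))
}

#' @export
print.cap_run <- function(x, ...) {
  cat(sprintf("<cap_run> k = %d, outputs in %s\n", x$extraction$caps$k, x$outdir))
  invisible(x)
}
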