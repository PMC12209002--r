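#' Generative state model for synthetic BOLD cohorts
#'
#' A hidden-Markov co-activation model: `K` co-activation states, each with a
#' whole-cortex spatial amplitude map, plus a baseline state (label 0) that
#' emits pure noise. At a CAP frame the signal is `a_t * map[s_t] + noise`
#' with `a_t ~ Normal(amplitude_mean, amplitude_sd)` and i.i.d. Gaussian
#' parcel noise. Every state loads positively on the designated seed parcels,
#' so seed-driven frame selection preferentially picks CAP frames — the
#' structure the co-activation pattern method assumes.
#'
#' Maps are drawn once from a standard normal, given a positive offset on the
#' seed parcels, and scaled to unit variance across parcels.
#'
#' @param n_states Number of co-activation states K.
#' @param n_parcels Number of parcels P.
#' @param seed_parcels Indices of the seed region (all states load on it).
#' @param transition_matrix `(K+1) x (K+1)` row-stochastic matrix over states
#'   `0..K` (baseline first). Default: moderately sticky chain, see
#'   [default_transition_matrix()].
#' @param amplitude_mean,amplitude_sd Per-frame activation magnitude.
#' @param noise_sd Additive parcel noise scale.
#' @param seed_loading Positive offset added to map entries on seed parcels
#'   before unit-variance scaling.
#' @param maps Optional `K x P` matrix of state maps; drawn if `NULL`.
#' @param rng_seed Seed used to draw the maps.
#' @return An object of class `state_model`.
#' @export
state_model <- function(n_states = 4, n_parcels = 90,
                        seed_parcels = 1:12,
                        transition_matrix = default_transition_matrix(n_states),
                        amplitude_mean = 1.5, amplitude_sd = 0.5,
                        noise_sd = 1, seed_loading = 1.5,
                        maps = NULL, rng_seed = 1L) {
  stopifnot(n_states >= 1, n_parcels >= 2)
  if (any(seed_parcels < 1) || any(seed_parcels > n_parcels)) {
    stop("`seed_parcels` must lie in [1, n_parcels].", call. = FALSE)
  }
  assert_row_stochastic(transition_matrix)
  if (nrow(transition_matrix) != n_states + 1) {
    stop("`transition_matrix` must be (K+1) x (K+1) including the baseline state.",
      call. = FALSE)
  }
  if (is.null(maps)) {
    maps <- with_seed(derive_seed(rng_seed, "maps"), {
      m <- matrix(stats::rnorm(n_states * n_parcels), n_states, n_parcels)
      m[, seed_parcels] <- abs(m[, seed_parcels]) + seed_loading
      m
    })
  }
  maps <- as.matrix(maps)
  if (!all(dim(maps) == c(n_states, n_parcels))) {
    stop("`maps` must be K x P.", call. = FALSE)
  }
  # unit variance across parcels per state (amplitude lives in a_t)
  maps <- maps / apply(maps, 1, stats::sd)
  structure(
    list(
      n_states = n_states, n_parcels = n_parcels, maps = maps,
      seed_parcels = as.integer(seed_parcels),
      transition_matrix = transition_matrix,
      amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
      noise_sd = noise_sd
    ),
    class = "state_model"
  )
}

#' Default transition matrix of the synthetic chain
#'
#' Baseline (state 0) is moderately sticky (self-transition 0.5) and feeds all
#' CAP states equally; CAP states persist with probability 0.6, return to
#' baseline with 0.2, and route most of the remaining mass to a preferred
#' next state (cyclically `s -> s+1`), with only a small probability of
#' jumping elsewhere. The uneven switching routes mirror the non-uniform
#' state-transition preferences seen in resting-state dynamics and give the
#' transition graph genuine path structure: weak direct links can be beaten
#' by two-hop routes, so betweenness centrality varies across subjects
#' instead of being identically zero. Stationary occupancy is roughly one
#' third baseline, the rest shared equally by the CAP states.
#'
#' @param n_states Number of CAP states K.
#' @param self_cap CAP self-transition probability (state stability).
#' @param cap_to_base Probability of returning to baseline from a CAP state.
#' @param self_base Baseline self-transition probability.
#' @param route_share Share of the remaining probability mass routed to the
#'   preferred next state (the rest is spread over the other states).
#' @return A `(K+1) x (K+1)` row-stochastic matrix.
#' @export
default_transition_matrix <- function(n_states = 4, self_cap = 0.6,
                                      cap_to_base = 0.2, self_base = 0.5,
                                      route_share = 0.8) {
  k1 <- n_states + 1
  P <- matrix(0, k1, k1)
  P[1, 1] <- self_base
  P[1, -1] <- (1 - self_base) / n_states
  rest <- 1 - self_cap - cap_to_base
  for (s in 2:k1) {
    P[s, s] <- self_cap
    P[s, 1] <- cap_to_base
    others <- setdiff(2:k1, s)
    if (length(others) > 0) {
      nxt <- if (s == k1) 2L else s + 1L
      weak <- setdiff(others, nxt)
      if (length(weak) > 0) {
        P[s, nxt] <- rest * route_share
        P[s, weak] <- rest * (1 - route_share) / length(weak)
      } else {
        P[s, nxt] <- rest
      }
    }
  }
  P
}

#' Sample a hidden state sequence from a Markov chain
#'
#' States are labeled `0..K` with 0 = baseline. The marginal state
#' frequencies converge to the chain's stationary distribution as the
#' sequence grows.
#'
#' @param transition_matrix Row-stochastic `(K+1) x (K+1)` matrix.
#' @param n_frames Sequence length (>= 1).
#' @param initial_distribution Probability vector over states `0..K`;
#'   defaults to the stationary distribution.
#' @param rng_seed Integer seed.
#' @return Integer vector of length `n_frames` with values in `0..K`.
#' @export
sample_state_sequence <- function(transition_matrix, n_frames,
                                  initial_distribution = NULL,
                                  rng_seed = 1L) {
  assert_row_stochastic(transition_matrix)
  stopifnot(n_frames >= 1)
  k1 <- nrow(transition_matrix)
  init <- initial_distribution %||% stationary_distribution(transition_matrix)
  if (length(init) != k1 || any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    stop("`initial_distribution` must be a probability vector over all states.",
      call. = FALSE)
  }
  with_seed(rng_seed, {
    seq_out <- integer(n_frames)
    s <- sample.int(k1, 1, prob = init)
    seq_out[1] <- s
    if (n_frames > 1) {
      for (t in 2:n_frames) {
        s <- sample.int(k1, 1, prob = transition_matrix[s, ])
        seq_out[t] <- s
      }
    }
    seq_out - 1L  # labels 0..K
  })
}

#' Generate one subject-session time series from a state sequence
#'
#' CAP frames are `a_t * map[s_t] + noise`; baseline frames are pure noise.
#' The result carries the TR and an all-usable censoring mask.
#'
#' @param model A [state_model].
#' @param sequence Integer state labels in `0..K`.
#' @param tr_seconds Repetition time.
#' @param subject_id,session_id Identifiers.
#' @param rng_seed Integer seed.
#' @return A [parcel_ts].
#' @export
generate_subject_timeseries <- function(model, sequence, tr_seconds = 2,
                                        subject_id = NA_character_,
                                        session_id = NA_character_,
                                        rng_seed = 1L) {
  stopifnot(inherits(model, "state_model"))
  sequence <- as.integer(sequence)
  if (any(sequence < 0) || any(sequence > model$n_states)) {
    stop("sequence labels must lie in 0..K.", call. = FALSE)
  }
  T_ <- length(sequence)
  P <- model$n_parcels
  vals <- with_seed(rng_seed, {
    amp <- stats::rnorm(T_, model$amplitude_mean, model$amplitude_sd)
    eps <- matrix(stats::rnorm(T_ * P, 0, model$noise_sd), T_, P)
    sig <- matrix(0, T_, P)
    cap <- sequence > 0
    if (any(cap)) {
      sig[cap, ] <- amp[cap] * model$maps[sequence[cap], , drop = FALSE]
    }
    sig + eps
  })
  parcel_ts(vals,
    tr_seconds = tr_seconds,
    subject_id = subject_id, session_id = session_id
  )
}

#' Cohort specification for the synthetic study
#'
#' Defines the study conditions the generator emulates: 22 subjects scanned
#' pre- and 3 months post-surgery, neuropsychological scores (TMT-A, TMT-B,
#' TMT B-A, attentional matrices) at three timepoints (pre, 1 week, 3
#' months; imaging only at pre and 3 months), a deficit subgroup whose
#' designated FPN-like state is less stable and switches more, and a single
#' planted latent axis linking longitudinal changes in that state's
#' occurrence and resilience to longitudinal score changes.
#'
#' @param n_subjects Number of subjects (default 22).
#' @param n_frames Frames per session (default 180).
#' @param tr_seconds Repetition time (default 2 s).
#' @param n_states,n_parcels,seed_parcels Passed to [state_model()].
#' @param n_deficit Number of subjects in the post-surgical deficit group
#'   (default 10; the remainder are the no-deficit group).
#' @param stability_modifier Multiplier on the FPN-like state's
#'   self-transition probability for the deficit group (< 1 = less stable).
#' @param switching_modifier Multiplier on transitions into the FPN-like
#'   state from other states for the deficit group (> 1 = more switching).
#' @param fpn_state Which CAP state carries the group effect and the planted
#'   axis (default K, the last state).
#' @param behavior_params Per-score generative parameters; see
#'   [default_behavior_params()].
#' @param behavior_noise_sd Residual score noise (same scale as the scores).
#' @param seed Integer RNG seed governing the whole cohort. Per-subject
#'   streams are derived by stable hashing of (seed, subject, session), so
#'   adding subjects never perturbs existing ones.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 22, n_frames = 180, tr_seconds = 2,
                        n_states = 4, n_parcels = 90, seed_parcels = 1:12,
                        n_deficit = 10,
                        stability_modifier = 0.6, switching_modifier = 1.6,
                        fpn_state = n_states,
                        behavior_params = default_behavior_params(),
                        behavior_noise_sd = 2,
                        seed = 1L) {
  stopifnot(n_subjects >= 2, n_frames >= 2, n_deficit >= 0, n_deficit <= n_subjects)
  stopifnot(fpn_state >= 1, fpn_state <= n_states)
  subjects <- sprintf("sub%02d", seq_len(n_subjects))
  groups <- rep("no_deficit", n_subjects)
  groups[seq_len(n_deficit)] <- "deficit"
  structure(
    list(
      n_subjects = n_subjects, subjects = subjects,
      sessions = c("pre", "post3m"),
      timepoints = c("pre", "1w", "3m"),
      n_frames = n_frames, tr_seconds = tr_seconds,
      n_states = n_states, n_parcels = n_parcels, seed_parcels = seed_parcels,
      group_assignment = stats::setNames(groups, subjects),
      stability_modifier = stability_modifier,
      switching_modifier = switching_modifier,
      fpn_state = fpn_state,
      behavior_params = behavior_params,
      behavior_noise_sd = behavior_noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Default generative parameters of the behavioral scores
#'
#' Scores are on the age/education-adjusted scale the pipeline consumes.
#' `loading` links each score's 3-month change to the planted latent axis
#' (standardized combination of the FPN-like state's occurrence and
#' resilience changes); TMT loadings are negative — increased occurrence and
#' resilience go with *lower* (better) completion-time changes — while the
#' attentional-matrices loading is positive (higher = better).
#' `deficit_shift_1w` pushes the deficit group past the clinical cutoff one
#' week after surgery; by three months scores regress to the pre-surgical
#' level. TMT B-A is derived as TMT-B minus TMT-A, never drawn.
#'
#' @return A tibble with one row per directly generated score.
#' @export
default_behavior_params <- function() {
  tibble::tibble(
    score = c("TMTA", "TMTB", "AttentionalMatrices"),
    orientation = c("higher_worse", "higher_worse", "higher_better"),
    intercept = c(45, 100, 48),
    cutoff = c(94, 283, 31),
    deficit_shift_1w = c(65, 200, -22),
    loading = c(-4, -6, 2)
  )
}

cutoff_tmtba <- 187  # derived-score cutoff on the adjusted scale

#' Apply deficit-group modifiers to a transition matrix
#'
#' The FPN-like state's self-transition is multiplied by
#' `stability_modifier` and transitions into it from every other state by
#' `switching_modifier`; each affected row is renormalized over its remaining
#' entries so all rows stay stochastic.
#'
#' @param P `(K+1) x (K+1)` row-stochastic matrix, baseline first.
#' @param fpn_state CAP state index in `1..K`.
#' @param stability_modifier,switching_modifier Multipliers (identity = 1).
#' @return A row-stochastic matrix.
#' @export
apply_group_effects <- function(P, fpn_state, stability_modifier = 1,
                                switching_modifier = 1) {
  assert_row_stochastic(P)
  f <- fpn_state + 1L  # matrix index (baseline is row/col 1)
  # destabilize: shrink self-transition, spread freed mass over the row
  P[f, f] <- P[f, f] * stability_modifier
  P[f, ] <- P[f, ] / sum(P[f, ])
  # switch more: inflate transitions into the state, renormalize each row
  for (i in seq_len(nrow(P))) {
    if (i == f) next
    P[i, f] <- P[i, f] * switching_modifier
    P[i, ] <- P[i, ] / sum(P[i, ])
  }
  assert_row_stochastic(P, tol = 1e-9)
  P
}

#' Generate behavioral scores with a planted brain-behavior axis
#'
#' Per subject, the latent projection is the standardized sum of the
#' standardized session differences (post minus pre) of the FPN-like state's
#' occurrence and resilience. Each directly generated score is
#' `intercept + noise` pre-surgery, shifted past its cutoff at 1 week for the
#' deficit group, and `intercept + loading * latent + noise` at 3 months
#' (regressing to the pre-surgical level in expectation). TMT B-A is computed
#' as TMT-B minus TMT-A at every timepoint, preserving the identity exactly.
#'
#' @param metrics Tidy temporal-metrics tibble with columns `subject`,
#'   `session`, `state`, `metric`, `value` covering both sessions.
#' @param spec A [cohort_spec].
#' @param rng_seed Integer seed.
#' @return A behavior tibble (`subject`, `timepoint`, `score`, `value`,
#'   `cutoff`, `orientation`).
#' @export
generate_behavior <- function(metrics, spec, rng_seed = derive_seed(spec$seed, "behavior")) {
  stopifnot(inherits(spec, "cohort_spec"))
  need <- tidyr::expand_grid(
    subject = spec$subjects, session = spec$sessions,
    metric = c("occurrence", "resilience")
  )
  have <- dplyr::filter(metrics, .data$state == spec$fpn_state)
  chk <- dplyr::anti_join(need, have, by = c("subject", "session", "metric"))
  if (nrow(chk) > 0) {
    stop(sprintf("metrics table is missing rows for subject(s): %s.",
      paste(unique(chk$subject), collapse = ", ")), call. = FALSE)
  }

  deltas <- have |>
    dplyr::filter(.data$metric %in% c("occurrence", "resilience")) |>
    dplyr::select("subject", "session", "metric", "value") |>
    tidyr::pivot_wider(names_from = "session", values_from = "value") |>
    dplyr::mutate(delta = .data$post3m - .data$pre) |>
    dplyr::select("subject", "metric", "delta") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "delta")

  z_safe <- function(x) if (stats::sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / stats::sd(x)
  latent_raw <- z_safe(deltas$occurrence) + z_safe(deltas$resilience)
  latent <- stats::setNames(z_safe(latent_raw), deltas$subject)

  bp <- spec$behavior_params
  grid <- tidyr::expand_grid(subject = spec$subjects, score = bp$score,
    timepoint = spec$timepoints)
  rows <- with_seed(rng_seed, {
    noise <- stats::rnorm(nrow(grid), 0, spec$behavior_noise_sd)
    grid |>
      dplyr::left_join(bp, by = "score") |>
      dplyr::mutate(
        group = unname(spec$group_assignment[.data$subject]),
        value = .data$intercept + noise +
          ifelse(.data$timepoint == "1w" & .data$group == "deficit",
            .data$deficit_shift_1w, 0) +
          ifelse(.data$timepoint == "3m",
            .data$loading * unname(latent[.data$subject]), 0)
      )
  })
  direct <- dplyr::select(rows, "subject", "timepoint", "score", "value",
    "cutoff", "orientation")
  tmtba <- direct |>
    dplyr::filter(.data$score %in% c("TMTA", "TMTB")) |>
    tidyr::pivot_wider(names_from = "score", values_from = "value",
      id_cols = c("subject", "timepoint")) |>
    dplyr::mutate(
      score = "TMTBA", value = .data$TMTB - .data$TMTA,
      cutoff = cutoff_tmtba, orientation = "higher_worse"
    ) |>
    dplyr::select("subject", "timepoint", "score", "value", "cutoff", "orientation")
  dplyr::arrange(dplyr::bind_rows(direct, tmtba),
    .data$subject, .data$timepoint, .data$score)
}

#' Generate a complete synthetic cohort
#'
#' Deterministic given `spec$seed`: the state model, per-subject-session
#' hidden state sequences and time series, planted temporal metrics, behavior
#' table and manifest. Ground truth (model, sequences, group labels, planted
#' transition matrices) is retained for recovery tests.
#'
#' @param spec A [cohort_spec].
#' @return A list of class `cap_cohort` with elements `manifest`,
#'   `timeseries` (named list of [parcel_ts]), `behavior`, `metrics`
#'   (planted-sequence metrics), `model`, `sequences`, `transition_matrices`,
#'   `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  model <- state_model(
    n_states = spec$n_states, n_parcels = spec$n_parcels,
    seed_parcels = spec$seed_parcels, rng_seed = derive_seed(spec$seed, "model")
  )
  P_by_group <- list(
    no_deficit = model$transition_matrix,
    deficit = apply_group_effects(model$transition_matrix, spec$fpn_state,
      spec$stability_modifier, spec$switching_modifier)
  )
  grid <- tidyr::expand_grid(subject = spec$subjects, session = spec$sessions)
  sequences <- list()
  timeseries <- list()
  for (i in seq_len(nrow(grid))) {
    sub <- grid$subject[i]
    ses <- grid$session[i]
    gr <- spec$group_assignment[[sub]]
    key <- paste(sub, ses, sep = "_")
    sq <- sample_state_sequence(
      P_by_group[[gr]], spec$n_frames,
      rng_seed = derive_seed(spec$seed, sub, ses, "seq")
    )
    sequences[[key]] <- sq
    timeseries[[key]] <- generate_subject_timeseries(
      model, sq,
      tr_seconds = spec$tr_seconds, subject_id = sub, session_id = ses,
      rng_seed = derive_seed(spec$seed, sub, ses, "ts")
    )
  }
  manifest <- dplyr::mutate(grid,
    group = unname(spec$group_assignment[.data$subject]),
    path = paste0(.data$subject, "_", .data$session, ".tsv")
  )
  metrics <- cohort_metrics(
    tibble::tibble(
      subject = grid$subject, session = grid$session,
      sequence = unname(sequences[paste(grid$subject, grid$session, sep = "_")])
    ),
    tr_seconds = spec$tr_seconds, k = spec$n_states
  )
  behavior <- generate_behavior(metrics, spec)
  structure(
    list(
      manifest = manifest, timeseries = timeseries, behavior = behavior,
      metrics = metrics, model = model, sequences = sequences,
      transition_matrices = P_by_group, spec = spec
    ),
    class = "cap_cohort"
  )
}

#' @export
print.cap_cohort <- function(x, ...) {
  cat(sprintf(
    "<cap_cohort> %d subjects x %d sessions, %d frames x %d parcels, K = %d\n",
    x$spec$n_subjects, length(x$spec$sessions), x$spec$n_frames,
    x$spec$n_parcels, x$spec$n_states
  ))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Time series as TSV (one file per subject-session), manifest and behavior
#' as CSV, ground truth (maps, transition matrices, sequences, seed) as JSON.
#'
#' @param cohort A `cap_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cap_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$manifest))) {
    write_timeseries(
      cohort$timeseries[[paste(cohort$manifest$subject[i],
        cohort$manifest$session[i], sep = "_")]],
      file.path(dir, cohort$manifest$path[i])
    )
  }
  readr::write_csv(cohort$manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  readr::write_csv(cohort$behavior, file.path(dir, "behavior.csv"), progress = FALSE)
  truth <- list(
    seed = cohort$spec$seed,
    maps = cohort$model$maps,
    transition_matrices = cohort$transition_matrices,
    group_assignment = as.list(cohort$spec$group_assignment),
    sequences = cohort$sequences
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
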