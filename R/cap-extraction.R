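#' Frame selection policy
#'
#' How frames are picked for clustering from the seed signal: either the top
#' fraction of usable frames by seed z-score (default 15%, the dominant
#' convention in the co-activation pattern literature) or all frames above a
#' z threshold. With `polarity = "both"`, matching co-deactivation frames
#' (lowest / below `-z_cut`) are also returned and stored sign-flipped so
#' that activation and deactivation events share one cluster space.
#'
#' @param mode `"top_fraction"` or `"z_threshold"`.
#' @param fraction Fraction of usable frames kept in `top_fraction` mode.
#' @param z_cut Threshold in `z_threshold` mode (applied to the
#'   re-standardized seed signal).
#' @param polarity `"activation"` or `"both"`.
#' @return An object of class `frame_policy`.
#' @export
frame_policy <- function(mode = c("top_fraction", "z_threshold"),
                         fraction = 0.15, z_cut = 1.0,
                         polarity = c("activation", "both")) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  if (mode == "top_fraction" && (fraction <= 0 || fraction > 1)) {
    stop("`fraction` must be in (0, 1].", call. = FALSE)
  }
  structure(list(mode = mode, fraction = fraction, z_cut = z_cut,
    polarity = polarity), class = "frame_policy")
}

#' Z-score a run parcel-wise
#'
#' Per parcel, over usable frames only: mean 0, population SD 1. Censored
#' frames are passed through untouched (they stay flagged by the censor mask
#' and never enter clustering). A zero-variance parcel is an error by
#' default, or silently dropped with `on_constant = "drop"`.
#'
#' @param series A [parcel_ts].
#' @param on_constant `"error"` or `"drop"` for zero-variance parcels.
#' @return A z-scored [parcel_ts].
#' @export
zscore_run <- function(series, on_constant = c("error", "drop")) {
  stopifnot(inherits(series, "parcel_ts"))
  on_constant <- match.arg(on_constant)
  use <- series$censor_mask
  if (sum(use) < 2) stop("need at least 2 usable frames to z-score.", call. = FALSE)
  vals <- series$values
  mu <- colMeans(vals[use, , drop = FALSE])
  sdv <- apply(vals[use, , drop = FALSE], 2, pop_sd)
  const <- which(sdv == 0)
  if (length(const) > 0) {
    if (on_constant == "error") {
      stop(sprintf("zero-variance parcel(s): %s.",
        paste(series$parcel_ids[const], collapse = ", ")), call. = FALSE)
    }
    vals <- vals[, -const, drop = FALSE]
    mu <- mu[-const]
    sdv <- sdv[-const]
    ids <- series$parcel_ids[-const]
  } else {
    ids <- series$parcel_ids
  }
  z <- sweep(sweep(vals, 2, mu), 2, sdv, "/")
  z[!use, ] <- vals[!use, , drop = FALSE]  # censored frames untouched
  parcel_ts(z,
    tr_seconds = series$tr_seconds, censor_mask = use,
    subject_id = series$subject_id, session_id = series$session_id,
    parcel_ids = ids
  )
}

#' Seed signal of a run
#'
#' Mean of the seed parcels per frame, re-standardized over usable frames
#' (mean 0, population SD 1). Censored frames get `NA`.
#' @noRd
seed_signal <- function(series, seed) {
  stopifnot(inherits(series, "parcel_ts"), inherits(seed, "seed_definition"))
  if (any(seed$parcel_indices > ncol(series$values))) {
    stop("seed parcel indices exceed the number of parcels.", call. = FALSE)
  }
  s <- rowMeans(series$values[, seed$parcel_indices, drop = FALSE])
  use <- series$censor_mask
  z <- rep(NA_real_, length(s))
  sdv <- pop_sd(s[use])
  if (sdv == 0) stop("seed signal has zero variance over usable frames.", call. = FALSE)
  z[use] <- (s[use] - mean(s[use])) / sdv
  z
}

#' Select frames for CAP clustering
#'
#' Picks the frames on which the seed system is most (co-)active. In
#' `top_fraction` mode, `ceiling(fraction * n_usable)` usable frames with the
#' highest seed z are returned (with `polarity = "both"`, also the matching
#' lowest frames, to be sign-flipped before clustering); in `z_threshold`
#' mode, all usable frames beyond the cut. Censored frames are never
#' selected; returned indices are strictly increasing.
#'
#' @param series A z-scored [parcel_ts].
#' @param seed A [seed_definition].
#' @param policy A [frame_policy].
#' @return A list with `activation` (integer frame indices), `deactivation`
#'   (indices, empty unless `polarity = "both"`), and `seed_z` (per-frame
#'   seed z-score, `NA` at censored frames).
#' @export
select_frames <- function(series, seed, policy = frame_policy()) {
  z <- seed_signal(series, seed)
  usable <- which(series$censor_mask)
  if (policy$mode == "top_fraction") {
    n_sel <- ceiling(policy$fraction * length(usable))
    if (n_sel > length(usable)) {
      stop("fewer usable frames than requested selection count.", call. = FALSE)
    }
    ord <- usable[order(-z[usable], usable)]
    act <- sort(ord[seq_len(n_sel)])
    deact <- integer(0)
    if (policy$polarity == "both") {
      ord_lo <- usable[order(z[usable], usable)]
      deact <- sort(ord_lo[seq_len(n_sel)])
    }
  } else {
    act <- usable[z[usable] > policy$z_cut]
    deact <- if (policy$polarity == "both") usable[z[usable] < -policy$z_cut] else integer(0)
  }
  list(activation = act, deactivation = deact, seed_z = z)
}

# -- correlation-distance k-means ---------------------------------------------

# rows centered and scaled to unit norm, so that cosine similarity of
# normalized rows equals the Pearson correlation of the raw rows
normalize_rows <- function(X) {
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  zero <- nrm == 0
  if (any(zero)) {
    nrm[zero] <- 1
    Xc[zero, ] <- 0
  }
  list(X = Xc / nrm, zero = zero)
}

# greedy k-means++ seeding on 1 - correlation distance
kmeanspp_init <- function(Xn, k) {
  n <- nrow(Xn)
  n_cand <- 2L + floor(log(k))
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d <- 1 - drop(Xn %*% Xn[centers[1], ])
  d[d < 0] <- 0
  if (k > 1) {
    for (j in 2:k) {
      cand <- sample.int(n, min(n_cand, n), prob = pmax(d, 1e-300), replace = FALSE)
      best_pot <- Inf
      best_c <- cand[1]
      best_d <- d
      for (cc in cand) {
        dc <- pmin(d, 1 - drop(Xn %*% Xn[cc, ]))
        pot <- sum(dc)
        if (pot < best_pot) {
          best_pot <- pot
          best_c <- cc
          best_d <- dc
        }
      }
      centers[j] <- best_c
      d <- best_d
    }
  }
  centers
}

# one Lloyd run of spherical (correlation-distance) k-means; returns NULL on
# an empty cluster so the caller can reseed
kmeans_corr_once <- function(X, Xn, k, max_iter) {
  C <- Xn[kmeanspp_init(Xn, k), , drop = FALSE]
  labels <- integer(nrow(X))
  obj_prev <- Inf
  for (iter in seq_len(max_iter)) {
    sim <- Xn %*% t(C)
    new_labels <- max.col(sim, ties.method = "first")
    obj <- sum(1 - sim[cbind(seq_len(nrow(X)), new_labels)])
    # spherical updates cannot increase the within-cluster correlation distance
    stopifnot(obj <= obj_prev + 1e-9)
    obj_prev <- obj
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      members <- labels == j
      if (!any(members)) return(NULL)
      cm <- colMeans(Xn[members, , drop = FALSE])
      nrm <- sqrt(sum(cm^2))
      if (nrm == 0) return(NULL)
      C[j, ] <- cm / nrm
    }
  }
  list(labels = labels, objective = obj_prev)
}

#' K-means clustering of selected frames into CAPs
#'
#' Clusters frames with distance `1 - Pearson correlation` (spatial-pattern
#' matching, amplitude-invariant) using greedy k-means++ seeding and
#' restarts; the restart with the lowest total within-cluster distance wins.
#' Each CAP map is the plain mean of its member frames (so co-deactivations
#' appear as negative map values). CAPs are renumbered in descending member
#' count, ties by first member frame, making runs reproducible bit-for-bit
#' at a fixed seed.
#'
#' If some cluster empties during a run the run is reseeded (fresh
#' derived seed); inputs with fewer distinct patterns than `k` are allowed
#' to keep empty clusters after the reseeding budget is exhausted.
#'
#' @param frames `N x P` matrix of selected (sign-aligned) frames.
#' @param k Model order (`N >= k`).
#' @param rng_seed Integer seed.
#' @param n_restarts Number of k-means restarts (default 20).
#' @param max_iter Lloyd iteration cap per restart.
#' @return A list of class `cap_set`: `maps` (`k x P`), `k`, `labels`
#'   (per-frame CAP index), `member_counts`, `objective`.
#' @export
kmeans_caps <- function(frames, k, rng_seed = 1L, n_restarts = 20L,
                        max_iter = 300L) {
  frames <- as.matrix(frames)
  N <- nrow(frames)
  if (N < k) stop(sprintf("need at least k = %d frames, got %d.", k, N), call. = FALSE)
  nz <- normalize_rows(frames)
  if (any(nz$zero)) {
    warning(sprintf("%d zero-variance frame(s); correlations treated as 0.",
      sum(nz$zero)))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(rng_seed, "kmeans", r), {
      out <- NULL
      for (attempt in 1:5) {
        out <- kmeans_corr_once(frames, nz$X, k, max_iter)
        if (!is.null(out)) break
      }
      out
    })
    if (is.null(fit)) {
      # degenerate input (fewer distinct patterns than k): single cluster
      # assignment by nearest of the distinct rows
      fit <- list(labels = rep(1L, N), objective = Inf)
    }
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  labels <- best$labels
  counts <- tabulate(labels, nbins = k)
  first_member <- vapply(seq_len(k), function(j) {
    w <- which(labels == j)
    if (length(w) == 0) N + 1L else w[1]
  }, integer(1))
  ord <- order(-counts, first_member)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[labels]
  counts <- counts[ord]
  maps <- matrix(0, k, ncol(frames))
  for (j in seq_len(k)) {
    members <- labels == j
    if (any(members)) maps[j, ] <- colMeans(frames[members, , drop = FALSE])
  }
  colnames(maps) <- colnames(frames)
  structure(
    list(maps = maps, k = k, labels = labels, member_counts = counts,
      objective = best$objective),
    class = "cap_set"
  )
}

#' @export
print.cap_set <- function(x, ...) {
  cat(sprintf("<cap_set> k = %d CAPs over %d parcels; member counts: %s\n",
    x$k, ncol(x$maps), paste(x$member_counts, collapse = ", ")))
  invisible(x)
}

#' Consensus clustering for model-order selection
#'
#' Repeatedly applies k-means to random subsamples of the frames and
#' evaluates the consistency of cluster assignments. For each candidate
#' order, the consensus of a frame pair is the fraction of co-inclusions in
#' which the pair was co-assigned; the PAC score (proportion of ambiguous
#' clustering) is the fraction of off-diagonal consensus entries strictly
#' inside `(lower, upper)`. The selected order minimizes PAC, ties going to
#' the smaller order. Pairs never co-included are excluded from PAC.
#'
#' @param frames `N x P` matrix of selected frames.
#' @param k_range Candidate model orders (each in `[2, N/2]`).
#' @param n_resamples Number of subsamples per order (>= 2; default 100).
#' @param subsample_fraction Fraction of frames per subsample (default 0.8,
#'   drawn without replacement).
#' @param rng_seed Integer seed.
#' @param n_restarts K-means restarts per subsample fit (default 5; the
#'   resampling itself supplies the robustness, so fewer restarts than a
#'   final fit are needed).
#' @param lower,upper PAC ambiguity band (default 0.1, 0.9).
#' @return A list of class `consensus_report`: per-order tibble `summary`
#'   (`k`, `pac`, `mean_consensus`), `selected_k`, `consensus` (list of
#'   consensus matrices), and the resampling settings.
#' @export
consensus_select_k <- function(frames, k_range = 2:8, n_resamples = 100L,
                               subsample_fraction = 0.8, rng_seed = 1L,
                               n_restarts = 1L, lower = 0.1, upper = 0.9) {
  frames <- as.matrix(frames)
  N <- nrow(frames)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > N / 2)) {
    stop("each k in `k_range` must lie in [2, N/2].", call. = FALSE)
  }
  if (n_resamples < 2) stop("`n_resamples` must be >= 2.", call. = FALSE)
  m <- max(2L, round(subsample_fraction * N))
  consensus <- list()
  summary <- tibble::tibble(k = k_range, pac = NA_real_, mean_consensus = NA_real_)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    co_inc <- matrix(0, N, N)
    co_asn <- matrix(0, N, N)
    for (r in seq_len(n_resamples)) {
      idx <- with_seed(derive_seed(rng_seed, "subsample", k, r),
        sort(sample.int(N, m)))
      fit <- kmeans_caps(frames[idx, , drop = FALSE], k,
        rng_seed = derive_seed(rng_seed, "fit", k, r), n_restarts = n_restarts)
      Z <- matrix(0, m, k)
      Z[cbind(seq_len(m), fit$labels)] <- 1
      co_inc[idx, idx] <- co_inc[idx, idx] + 1
      co_asn[idx, idx] <- co_asn[idx, idx] + tcrossprod(Z)
    }
    cons <- matrix(NA_real_, N, N)
    defined <- co_inc > 0
    cons[defined] <- co_asn[defined] / co_inc[defined]
    off <- cons[upper.tri(cons)]
    off <- off[!is.na(off)]
    summary$pac[ki] <- mean(off > lower & off < upper)
    summary$mean_consensus[ki] <- mean(off)
    consensus[[as.character(k)]] <- cons
  }
  selected_k <- summary$k[which.min(summary$pac)]  # which.min takes first = smaller k
  structure(
    list(summary = summary, selected_k = selected_k, consensus = consensus,
      k_range = k_range, n_resamples = n_resamples,
      subsample_fraction = subsample_fraction, rng_seed = rng_seed),
    class = "consensus_report"
  )
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> selected k = %d (PAC over k = %s)\n",
    x$selected_k,
    paste(sprintf("%d: %.3f", x$summary$k, x$summary$pac), collapse = ", ")))
  invisible(x)
}

#' Assign every frame of a run to a CAP state
#'
#' Frames passing the selection policy get the label of the CAP map with the
#' highest spatial (Pearson) correlation; ties go to the lower CAP index.
#' Other usable frames are labeled baseline (0); censored frames are `NA`.
#' A selected frame with zero spatial variance cannot be correlated and
#' falls back to baseline with a warning.
#'
#' @param series A z-scored [parcel_ts].
#' @param caps A `cap_set`.
#' @param seed A [seed_definition].
#' @param policy A [frame_policy].
#' @return Integer state sequence of length `n_frames` (`NA` = censored).
#' @export
assign_states <- function(series, caps, seed, policy = frame_policy()) {
  stopifnot(inherits(caps, "cap_set"))
  if (ncol(series$values) != ncol(caps$maps)) {
    stop("series and CAP maps must share the parcel order.", call. = FALSE)
  }
  sel <- select_frames(series, seed, policy)
  out <- rep(NA_integer_, nrow(series$values))
  out[series$censor_mask] <- 0L
  picked <- c(sel$activation, sel$deactivation)
  signs <- c(rep(1, length(sel$activation)), rep(-1, length(sel$deactivation)))
  if (length(picked) > 0) {
    F_ <- series$values[picked, , drop = FALSE] * signs
    fn <- normalize_rows(F_)
    if (any(fn$zero)) {
      warning(sprintf("%d selected frame(s) with zero variance labeled baseline.",
        sum(fn$zero)))
    }
    cn <- normalize_rows(caps$maps)
    sim <- fn$X %*% t(cn$X)
    lab <- max.col(sim, ties.method = "first")
    lab[fn$zero] <- 0L
    out[picked] <- as.integer(lab)
  }
  out
}

#' Run the pooled CAP extraction across a cohort
#'
#' Z-scores every run, selects frames with the policy, pools the selected
#' frames across all subjects and both sessions (so pre- and post-surgical
#' data share one state space and longitudinal differences are meaningful),
#' optionally selects the model order by consensus, fits the final k-means,
#' and assigns every frame of every run to a state.
#'
#' @param runs Named list of [parcel_ts] (names `subject_session`).
#' @param seed A [seed_definition].
#' @param policy A [frame_policy].
#' @param k Fixed model order, or `NULL` to select by consensus.
#' @param k_range,n_resamples,subsample_fraction,consensus_restarts Consensus
#'   settings (used when `k` is `NULL`).
#' @param n_restarts Restarts of the final k-means fit.
#' @param rng_seed Integer seed.
#' @return A list of class `cap_extraction`: `caps` (`cap_set`), `consensus`
#'   (`consensus_report` or `NULL`), `sequences` (tibble `subject`,
#'   `session`, list-column `sequence`), `selected` (tibble of pooled
#'   selected frames per run), `policy`, `seed`.
#' @export
extract_caps <- function(runs, seed, policy = frame_policy(), k = NULL,
                         k_range = 2:8, n_resamples = 100L,
                         subsample_fraction = 0.8, consensus_restarts = 1L,
                         n_restarts = 20L, rng_seed = 1L) {
  stopifnot(length(runs) > 0)
  zruns <- lapply(runs, zscore_run)
  pooled <- list()
  sel_index <- list()
  for (nm in names(zruns)) {
    sel <- select_frames(zruns[[nm]], seed, policy)
    F_ <- zruns[[nm]]$values[sel$activation, , drop = FALSE]
    if (length(sel$deactivation) > 0) {
      F_ <- rbind(F_, -zruns[[nm]]$values[sel$deactivation, , drop = FALSE])
    }
    pooled[[nm]] <- F_
    sel_index[[nm]] <- tibble::tibble(
      run = nm, frame = c(sel$activation, sel$deactivation),
      sign = c(rep(1, length(sel$activation)), rep(-1, length(sel$deactivation)))
    )
  }
  frames <- do.call(rbind, pooled)
  consensus <- NULL
  if (is.null(k)) {
    consensus <- consensus_select_k(frames, k_range, n_resamples,
      subsample_fraction, rng_seed = derive_seed(rng_seed, "consensus"),
      n_restarts = consensus_restarts)
    k <- consensus$selected_k
  }
  caps <- kmeans_caps(frames, k, rng_seed = derive_seed(rng_seed, "final"),
    n_restarts = n_restarts)
  seqs <- tibble::tibble(
    subject = vapply(zruns, function(r) r$subject_id, character(1)),
    session = vapply(zruns, function(r) r$session_id, character(1)),
    sequence = lapply(zruns, assign_states, caps = caps, seed = seed,
      policy = policy)
  )
  structure(
    list(caps = caps, consensus = consensus, sequences = seqs,
      selected = dplyr::bind_rows(sel_index), policy = policy, seed = seed),
    class = "cap_extraction"
  )
}
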