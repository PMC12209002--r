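#' Transition counts of a state sequence
#'
#' Counts usable consecutive frame pairs; pairs straddling a censored frame
#' (`NA` label) are skipped, so scrubbed gaps never create spurious
#' transitions.
#'
#' @param sequence Integer labels in `0..k`, `NA` = censored frame.
#' @param k Number of CAP states (labels run `0..k`, 0 = baseline).
#' @return `(k+1) x (k+1)` count matrix with dimnames `"0".."k"`;
#'   `N[i, j]` counts pairs state `i-1` then `j-1`.
#' @export
transition_counts <- function(sequence, k) {
  sequence <- as.integer(sequence)
  if (length(sequence) == 0) stop("sequence must be non-empty.", call. = FALSE)
  ok <- !is.na(sequence)
  if (any(sequence[ok] < 0 | sequence[ok] > k)) {
    stop(sprintf("sequence labels must lie in 0..%d.", k), call. = FALSE)
  }
  N <- matrix(0, k + 1, k + 1, dimnames = list(0:k, 0:k))
  if (length(sequence) < 2) return(N)
  a <- sequence[-length(sequence)]
  b <- sequence[-1]
  keep <- !is.na(a) & !is.na(b)
  if (any(keep)) {
    tab <- table(factor(a[keep], levels = 0:k), factor(b[keep], levels = 0:k))
    N <- N + unclass(tab)
  }
  N
}

#' Per-state betweenness centrality of the transition graph
#'
#' The directed graph has a node for every state with nonzero flow and an
#' edge `i -> j` wherever `N[i, j] > 0` (`i != j`), with length
#' `-log(p_ij)` where `p_ij` is the row-normalized between-state transition
#' probability — high-probability routes are short, and lengths add along
#' paths. A node's betweenness is the average, over all ordered source-target
#' pairs not involving it that are connected by some path, of the fraction of
#' shortest paths passing through it; it therefore lies in `[0, 1]`, and a
#' pure relay node on a single chain scores 1. Graphs with fewer than three
#' flowing nodes have no possible intermediaries and return all zeros.
#'
#' @param counts Transition count matrix from [transition_counts()].
#' @param tol Tolerance for recognizing tied shortest-path lengths
#'   (probability-derived weights produce exact ties that naive float
#'   comparison would miss).
#' @return Named numeric vector over all states `0..k`.
#' @export
betweenness_centrality <- function(counts, tol = 1e-9) {
  k1 <- nrow(counts)
  out <- stats::setNames(rep(0, k1), rownames(counts) %||% as.character(seq_len(k1) - 1))
  off <- counts
  diag(off) <- 0
  flow <- rowSums(off) + colSums(off)
  nodes <- which(flow > 0)
  if (length(nodes) < 3) return(out)
  sub <- off[nodes, nodes, drop = FALSE]
  rs <- rowSums(sub)
  p <- sub
  p[rs > 0, ] <- sub[rs > 0, , drop = FALSE] / rs[rs > 0]
  W <- matrix(Inf, length(nodes), length(nodes))
  W[sub > 0] <- pmax(-log(p[sub > 0]), 1e-12)
  bw <- brandes_betweenness(W, tol)
  out[nodes] <- bw
  out
}

# Brandes' algorithm (per-source Dijkstra with predecessor sets and backward
# dependency accumulation), with a tie tolerance, plus per-node normalization
# by the number of connected ordered pairs excluding the node
brandes_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  through <- numeric(n)  # sum over (s,t) pairs of sigma_st(v) / sigma_st
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0
    sigma[s] <- 1
    done <- logical(n)
    stack <- integer(0)  # settle order
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      stack <- c(stack, u)
      for (v in which(is.finite(W[u, ]))) {
        if (done[v]) next
        alt <- dist[u] + W[u, v]
        if (alt < dist[v] - tol) {
          dist[v] <- alt
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        } else if (abs(alt - dist[v]) <= tol) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    D[s, ] <- dist
    # backward dependency accumulation in reverse settle order
    delta <- numeric(n)
    for (w in rev(stack)) {
      for (u in preds[[w]]) {
        delta[u] <- delta[u] + sigma[u] / sigma[w] * (1 + delta[w])
      }
      if (w != s) through[w] <- through[w] + delta[w]
    }
  }
  out <- numeric(n)
  for (v in seq_len(n)) {
    conn <- is.finite(D)
    diag(conn) <- FALSE
    conn[v, ] <- FALSE
    conn[, v] <- FALSE
    denom <- sum(conn)
    out[v] <- if (denom > 0) through[v] / denom else 0
  }
  out
}

#' Temporal metrics of a state sequence
#'
#' Computes, for every state `0..k` (baseline included), the five temporal
#' metrics plus dwell duration:
#' * `occurrence` — fraction of usable frames in the state (sums to 1);
#' * `duration` — mean dwell length in seconds (consecutive-frame visits,
#'   split at censored gaps, times TR);
#' * `resilience` — self-transition probability `N[c,c] / sum_j N[c,j]`
#'   (0 with `visited = FALSE` for states never left from);
#' * `in_degree`, `out_degree` — share of all between-state switches that
#'   enter / leave the state (each sums to 1 over all states when any switch
#'   exists);
#' * `betweenness` — see [betweenness_centrality()].
#'
#' @param sequence Integer labels `0..k`, `NA` = censored.
#' @param tr_seconds Repetition time in seconds.
#' @param k Number of CAP states.
#' @return A tibble with one row per state `0..k`.
#' @export
compute_metrics <- function(sequence, tr_seconds, k) {
  sequence <- as.integer(sequence)
  usable <- sequence[!is.na(sequence)]
  if (length(usable) == 0) stop("all frames are censored.", call. = FALSE)
  if (any(usable > k)) stop(sprintf("labels must be <= k = %d.", k), call. = FALSE)
  states <- 0:k
  occ <- as.numeric(table(factor(usable, levels = states))) / length(usable)

  # dwell runs: split at censored gaps
  segs <- split(sequence[!is.na(sequence)],
    cumsum(is.na(sequence))[!is.na(sequence)])
  run_len <- list()
  for (seg in segs) {
    r <- rle(seg)
    for (i in seq_along(r$values)) {
      key <- as.character(r$values[i])
      run_len[[key]] <- c(run_len[[key]], r$lengths[i])
    }
  }
  duration <- vapply(as.character(states), function(s) {
    if (is.null(run_len[[s]])) 0 else mean(run_len[[s]]) * tr_seconds
  }, numeric(1))

  N <- transition_counts(sequence, k)
  rs <- rowSums(N)
  resilience <- ifelse(rs > 0, diag(N) / rs, 0)
  off <- N
  diag(off) <- 0
  total_switch <- sum(off)
  in_deg <- if (total_switch > 0) colSums(off) / total_switch else rep(0, k + 1)
  out_deg <- if (total_switch > 0) rowSums(off) / total_switch else rep(0, k + 1)
  btw <- betweenness_centrality(N)

  tibble::tibble(
    state = states,
    occurrence = occ,
    duration = unname(duration),
    resilience = unname(resilience),
    in_degree = unname(in_deg),
    out_degree = unname(out_deg),
    betweenness = unname(btw),
    visited = occ > 0
  )
}

#' Tidy temporal metrics for a table of sequences
#'
#' @param sequences A tibble with columns `subject`, `session`, and a
#'   list-column `sequence` of integer state vectors.
#' @param tr_seconds Repetition time.
#' @param k Number of CAP states.
#' @return A tidy tibble (`subject`, `session`, `state`, `metric`, `value`)
#'   covering states `0..k` and the six metrics.
#' @export
cohort_metrics <- function(sequences, tr_seconds, k) {
  stopifnot(all(c("subject", "session", "sequence") %in% names(sequences)))
  purrr::pmap_dfr(
    sequences[, c("subject", "session", "sequence")],
    function(subject, session, sequence) {
      m <- compute_metrics(sequence, tr_seconds, k)
      m$subject <- subject
      m$session <- session
      m
    }
  ) |>
    dplyr::select("subject", "session", "state", "occurrence", "duration",
      "resilience", "in_degree", "out_degree", "betweenness") |>
    tidyr::pivot_longer(
      cols = c("occurrence", "duration", "resilience", "in_degree",
        "out_degree", "betweenness"),
      names_to = "metric", values_to = "value"
    )
}

#' Longitudinal change in temporal metrics
#'
#' Post-surgical minus pre-surgical value per subject, state and metric.
#' Subjects lacking either session are dropped (the difference is undefined
#' for them).
#'
#' @param metrics Tidy metrics tibble from [cohort_metrics()].
#' @param from,to Session labels (default `pre` -> `post3m`).
#' @return A tibble (`subject`, `state`, `metric`, `delta`).
#' @export
longitudinal_delta <- function(metrics, from = "pre", to = "post3m") {
  wide <- metrics |>
    dplyr::filter(.data$session %in% c(from, to)) |>
    tidyr::pivot_wider(names_from = "session", values_from = "value")
  if (!all(c(from, to) %in% names(wide))) {
    stop(sprintf("sessions '%s' and '%s' not both present.", from, to), call. = FALSE)
  }
  wide |>
    dplyr::filter(!is.na(.data[[from]]) & !is.na(.data[[to]])) |>
    dplyr::mutate(delta = .data[[to]] - .data[[from]]) |>
    dplyr::select("subject", "state", "metric", "delta")
}
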