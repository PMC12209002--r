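# Independent oracles used across the suite. These deliberately use naive
# algorithms (exhaustive enumeration, closed forms) distinct from the
# package's implementations.

# all simple paths s -> t in a weighted directed graph given as a matrix of
# edge lengths (Inf = no edge); returns list of (length, path) pairs
all_simple_paths <- function(W, s, t) {
  n <- nrow(W)
  out <- list()
  walk <- function(v, visited, len) {
    if (v == t) {
      out[[length(out) + 1]] <<- list(length = len, path = visited)
      return()
    }
    for (w in seq_len(n)) {
      if (!is.finite(W[v, w]) || w %in% visited) next
      walk(w, c(visited, w), len + W[v, w])
    }
  }
  walk(s, s, 0)
  out
}

# brute-force betweenness: for each node v, average over connected ordered
# (s,t) pairs excluding v of the fraction of shortest s-t paths through v
brute_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  out <- numeric(n)
  for (v in seq_len(n)) {
    num <- 0
    denom <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        paths <- all_simple_paths(W, s, t)
        if (length(paths) == 0) next
        lens <- vapply(paths, `[[`, numeric(1), "length")
        mn <- min(lens)
        shortest <- paths[lens <= mn + tol]
        through <- vapply(shortest, function(p) v %in% p$path, logical(1))
        num <- num + mean(through)
        denom <- denom + 1
      }
    }
    out[v] <- if (denom > 0) num / denom else 0
  }
  out
}

# objective of a candidate frame partition under the package's clustering
# model: 1 - Pearson correlation to the spherical centroid of each cluster
partition_objective <- function(frames, labels) {
  rn <- t(apply(frames, 1, function(r) {
    rc <- r - mean(r)
    rc / sqrt(sum(rc^2))
  }))
  obj <- 0
  for (j in unique(labels)) {
    members <- rn[labels == j, , drop = FALSE]
    cm <- colMeans(members)
    cm <- cm / sqrt(sum(cm^2))
    obj <- obj + sum(1 - members %*% cm)
  }
  obj
}

# every partition of n items into exactly 2 non-empty clusters
two_partitions <- function(n) {
  out <- list()
  for (code in 1:(2^(n - 1) - 1)) {
    labels <- as.integer(intToBits(code))[1:n] + 1L
    out[[length(out) + 1]] <- labels
  }
  out
}

# closed-form REML variance components for a balanced one-way random-effects
# design (m subjects, r observations each, intercept-only mean)
balanced_reml <- function(y, subject) {
  m <- length(unique(subject))
  r <- as.integer(table(subject)[1])
  means <- tapply(y, subject, mean)
  msb <- r * sum((means - mean(y))^2) / (m - 1)
  msw <- sum((y - means[subject])^2) / (m * (r - 1))
  list(sigma2_subject = max((msb - msw) / r, 0), sigma2_residual = msw)
}

# small deterministic cohort used by several tests
tiny_cohort <- function(seed = 42, n_subjects = 8, n_frames = 120) {
  generate_cohort(cohort_spec(
    n_subjects = n_subjects, n_frames = n_frames, n_deficit = 4, seed = seed
  ))
}
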