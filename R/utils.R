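# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never clobbers
#' the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Derive a child seed from a parent seed and labels
#'
#' Stable integer hash of (seed, labels...). Adding subjects or sessions to a
#' cohort never perturbs the streams of existing ones.
#' @noRd
derive_seed <- function(seed, ...) {
  labs <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(labs)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

assert_row_stochastic <- function(P, tol = 1e-12, arg = "transition_matrix") {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop(sprintf("`%s` must be a square matrix.", arg), call. = FALSE)
  }
  if (any(P < 0)) {
    bad <- which(apply(P, 1, function(r) any(r < 0)))[1]
    stop(sprintf("`%s` has negative entries in row %d.", arg, bad), call. = FALSE)
  }
  rs <- rowSums(P)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0) {
    stop(sprintf(
      "`%s` row %d sums to %.15g, not 1.", arg, off[1], rs[off[1]]
    ), call. = FALSE)
  }
  invisible(P)
}

#' Stationary distribution of a row-stochastic matrix
#' @noRd
stationary_distribution <- function(P) {
  assert_row_stochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# population (1/n) standard deviation, the normalization used for run z-scoring
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

zscore_pop <- function(x) (x - mean(x)) / pop_sd(x)

# match estimated states to planted states by maximizing total map correlation
# (exhaustive over permutations for small k, as used throughout the recovery
# tests); returns the permutation p with p[estimated] = planted
match_states <- function(estimated_maps, planted_maps) {
  k <- nrow(estimated_maps)
  stopifnot(nrow(planted_maps) == k, k <= 8)
  cmat <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) cmat[i, j] <- stats::cor(estimated_maps[i, ], planted_maps[j, ])
  }
  perms <- permutations_of(k)
  best <- NULL
  best_val <- -Inf
  for (r in seq_len(nrow(perms))) {
    val <- sum(cmat[cbind(seq_len(k), perms[r, ])])
    if (val > best_val) {
      best_val <- val
      best <- perms[r, ]
    }
  }
  list(perm = best, correlations = cmat[cbind(seq_len(k), best)])
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1
  for (i in seq_len(n)) {
    for (s in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[r, ] <- c(i, rest[sub[s, ]])
      r <- r + 1
    }
  }
  out
}
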