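#' Paired t-test between sessions
#'
#' Thin, validated wrapper used for pre/post comparisons of scores and
#' temporal metrics: `t = mean(d) / (sd(d)/sqrt(n))` with `d = y - x`,
#' two-sided p from Student's t with `n - 1` degrees of freedom.
#'
#' @param x,y Paired per-subject values (same length, same subject order).
#' @return A one-row tibble (`t`, `df`, `p`, `mean_diff`, `n`).
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length.", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs.", call. = FALSE)
  d <- y - x
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: the paired t statistic is undefined.",
      call. = FALSE)
  }
  ht <- stats::t.test(y, x, paired = TRUE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
    mean_diff = mean(d), n = length(d)
  )
}

#' Pearson correlation with two-sided test
#'
#' @param x,y Numeric vectors (length >= 3, both non-constant).
#' @return A one-row tibble (`r`, `df`, `p`, `n`).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length.", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation is undefined.", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ht$estimate), df = unname(ht$parameter), p = ht$p.value,
    n = length(x)
  )
}

# z-score columns within each group (sample SD); errors on zero-variance
# columns naming them
group_zscore <- function(M, groups, what) {
  M <- as.matrix(M)
  out <- M
  for (g in unique(groups)) {
    rows <- groups == g
    sub <- M[rows, , drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    if (any(sds == 0)) {
      stop(sprintf("zero-variance %s column(s) within group '%s': %s.",
        what, g, paste(colnames(M)[sds == 0], collapse = ", ")), call. = FALSE)
    }
    out[rows, ] <- scale(sub)
  }
  out
}

plsc_cross_block <- function(Xz, Yz, groups) {
  glev <- unique(groups)
  R <- do.call(rbind, lapply(glev, function(g) {
    rows <- groups == g
    blk <- stats::cor(Yz[rows, , drop = FALSE], Xz[rows, , drop = FALSE])
    rownames(blk) <- paste(g, colnames(Yz), sep = ".")
    blk
  }))
  R
}

# SVD with the package's deterministic sign convention: the largest-|entry|
# element of each brain salience column is made positive
plsc_svd <- function(R) {
  sv <- svd(R)
  L <- length(sv$d)
  for (l in seq_len(L)) {
    j <- which.max(abs(sv$v[, l]))
    if (sv$v[j, l] < 0) {
      sv$v[, l] <- -sv$v[, l]
      sv$u[, l] <- -sv$u[, l]
    }
  }
  sv
}

#' Grouped behavioral partial least squares correlation
#'
#' Relates a brain block (e.g. per-subject longitudinal changes in the
#' temporal metrics of a CAP state) to a behavior block (score changes)
#' while disregarding absolute group differences: both blocks are z-scored
#' WITHIN each group, the group-wise behavior-by-brain correlation matrices
#' are stacked vertically, and the stack is decomposed by SVD. Each latent
#' component (LC) is a pair of saliences — a brain pattern and a per-group
#' behavior pattern — whose strength is the singular value. Latent scores
#' are the within-group z-scored data projected on the saliences. The
#' decomposition is deterministic up to a documented sign convention (the
#' largest-magnitude brain salience entry of each LC is positive).
#'
#' @param brain `n x B` numeric matrix or data frame (no missing values).
#' @param behavior `n x C` numeric matrix or data frame.
#' @param groups Length-`n` group labels (each group needs >= 3 subjects).
#'   A single shared group is used if omitted.
#' @return An object of class `plsc_fit`: `singular_values`,
#'   `brain_saliences` (`B x L`), `behavior_saliences` (`(G*C) x L`, rows
#'   labeled `group.score`), `latent_brain_scores`, `latent_behavior_scores`
#'   (`n x L`), `cross_block` (`R`), plus the inputs needed for resampling.
#' @export
plsc_fit <- function(brain, behavior, groups = NULL) {
  X <- as.matrix(brain)
  Y <- as.matrix(behavior)
  if (is.null(colnames(X))) colnames(X) <- paste0("brain", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("behavior", seq_len(ncol(Y)))
  n <- nrow(X)
  if (nrow(Y) != n) stop("brain and behavior must have the same rows.", call. = FALSE)
  if (anyNA(X) || anyNA(Y)) stop("missing values are not allowed.", call. = FALSE)
  groups <- groups %||% rep("all", n)
  if (length(groups) != n) stop("`groups` must have one label per subject.", call. = FALSE)
  small <- table(groups) < 3
  if (any(small)) {
    stop(sprintf("group(s) with fewer than 3 subjects: %s.",
      paste(names(small)[small], collapse = ", ")), call. = FALSE)
  }
  Xz <- group_zscore(X, groups, "brain")
  Yz <- group_zscore(Y, groups, "behavior")
  R <- plsc_cross_block(Xz, Yz, groups)
  sv <- plsc_svd(R)
  L <- length(sv$d)
  lx <- Xz %*% sv$v
  ly <- matrix(0, n, L)
  glev <- unique(groups)
  for (gi in seq_along(glev)) {
    rows <- groups == glev[gi]
    block <- sv$u[seq((gi - 1) * ncol(Y) + 1, gi * ncol(Y)), , drop = FALSE]
    ly[rows, ] <- Yz[rows, , drop = FALSE] %*% block
  }
  structure(
    list(
      singular_values = sv$d,
      brain_saliences = structure(sv$v, dimnames = list(colnames(X), NULL)),
      behavior_saliences = structure(sv$u, dimnames = list(rownames(R), NULL)),
      latent_brain_scores = lx, latent_behavior_scores = ly,
      cross_block = R, groups = groups, brain = X, behavior = Y
    ),
    class = "plsc_fit"
  )
}

#' @export
print.plsc_fit <- function(x, ...) {
  cat(sprintf("<plsc_fit> %d LCs; singular values: %s\n",
    length(x$singular_values),
    paste(sprintf("%.3f", x$singular_values), collapse = ", ")))
  invisible(x)
}

# procrustes rotation aligning the saliences of a refit to the original fit
procrustes_rotation <- function(V_ref, V_new) {
  a <- svd(crossprod(V_ref, V_new))
  a$v %*% t(a$u)
}

#' Permutation test of PLSC latent components
#'
#' Re-fits the decomposition with the behavior rows shuffled WITHIN group
#' (the exchangeability unit of the grouped analysis) and compares singular
#' values with the add-one estimator
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)`, so p-values never reach 0
#' and lie in `[1/(n_perm+1), 1]`. By default permuted singular values are
#' compared as-is; `procrustes = TRUE` first rotates each permuted salience
#' basis onto the observed one (this couples the null statistic to the
#' observed axes and is anti-conservative for the first LC, which is why raw
#' comparison is the default).
#'
#' Raw p-values are reported per LC together with Bonferroni-adjusted ones
#' (`p_adj`); because every LC of the decomposition is tested, counting
#' "significant" components on the adjusted scale keeps the family-wise
#' false-discovery of spurious extra components at the nominal level, which
#' matters when the question is *how many* axes link brain and behavior.
#'
#' @param fit A `plsc_fit`.
#' @param n_perm Number of permutations (default 1000; must be >= 1, a
#'   warning is issued below 100).
#' @param rng_seed Integer seed.
#' @param procrustes Align permuted saliences before comparing.
#' @param adjust Multiplicity adjustment for `p_adj` (default
#'   `"bonferroni"`, any [stats::p.adjust] method).
#' @return A tibble (`lc`, `singular_value`, `p`, `p_adj`).
#' @export
plsc_permutation <- function(fit, n_perm = 1000L, rng_seed = 1L,
                             procrustes = FALSE, adjust = "bonferroni") {
  stopifnot(inherits(fit, "plsc_fit"))
  if (n_perm < 1) stop("`n_perm` must be >= 1.", call. = FALSE)
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse.")
  L <- length(fit$singular_values)
  groups <- fit$groups
  Xz <- group_zscore(fit$brain, groups, "brain")
  count_ge <- rep(0, L)
  with_seed(rng_seed, {
    for (b in seq_len(n_perm)) {
      idx <- seq_along(groups)
      for (g in unique(groups)) {
        rows <- which(groups == g)
        idx[rows] <- rows[sample.int(length(rows))]
      }
      Yp <- fit$behavior[idx, , drop = FALSE]
      Yz <- group_zscore(Yp, groups, "behavior")
      Rp <- plsc_cross_block(Xz, Yz, groups)
      svp <- svd(Rp)
      if (procrustes) {
        rot <- procrustes_rotation(fit$brain_saliences, svp$v)
        aligned <- svp$v %*% diag(svp$d, L, L) %*% rot
        sp <- sqrt(colSums(aligned^2))
      } else {
        sp <- svp$d
      }
      count_ge <- count_ge + (sp >= fit$singular_values)
    }
  })
  p <- (1 + count_ge) / (1 + n_perm)
  tibble::tibble(
    lc = seq_len(L),
    singular_value = fit$singular_values,
    p = p,
    p_adj = stats::p.adjust(p, method = adjust)
  )
}

#' Bootstrap stability of PLSC saliences
#'
#' Resamples subjects with replacement WITHIN group, re-fits, aligns each
#' bootstrap's saliences to the original basis (Procrustes rotation computed
#' on the brain saliences and applied to both blocks), and reports empirical
#' 5th/95th percentile bounds per salience entry. An entry is flagged robust
#' when its interval excludes 0. Resamples producing a zero-variance column
#' are redrawn (at most 100 retries each).
#'
#' @param fit A `plsc_fit`.
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param rng_seed Integer seed.
#' @param probs Percentile bounds (default 5% and 95%).
#' @return A tibble (`block`, `variable`, `lc`, `salience`, `boot_low`,
#'   `boot_high`, `robust`).
#' @export
plsc_bootstrap <- function(fit, n_boot = 500L, rng_seed = 1L,
                           probs = c(0.05, 0.95)) {
  stopifnot(inherits(fit, "plsc_fit"))
  if (n_boot < 1) stop("`n_boot` must be >= 1.", call. = FALSE)
  L <- length(fit$singular_values)
  groups <- fit$groups
  B <- nrow(fit$brain_saliences)
  GC <- nrow(fit$behavior_saliences)
  v_draws <- array(NA_real_, c(B, L, n_boot))
  u_draws <- array(NA_real_, c(GC, L, n_boot))
  with_seed(rng_seed, {
    for (b in seq_len(n_boot)) {
      for (try in seq_len(100)) {
        idx <- integer(0)
        for (g in unique(groups)) {
          rows <- which(groups == g)
          idx <- c(idx, sample(rows, length(rows), replace = TRUE))
        }
        Xb <- fit$brain[idx, , drop = FALSE]
        Yb <- fit$behavior[idx, , drop = FALSE]
        gb <- groups[idx]
        ok <- tryCatch({
          Xz <- group_zscore(Xb, gb, "brain")
          Yz <- group_zscore(Yb, gb, "behavior")
          TRUE
        }, error = function(e) FALSE)
        if (ok) break
        if (try == 100) stop("could not draw a non-degenerate bootstrap sample.",
          call. = FALSE)
      }
      Rb <- plsc_cross_block(Xz, Yz, gb)
      svb <- svd(Rb)
      rot <- procrustes_rotation(fit$brain_saliences, svb$v)
      v_draws[, , b] <- svb$v %*% rot
      u_draws[, , b] <- svb$u %*% rot
    }
  })
  q_lo <- function(a) apply(a, c(1, 2), stats::quantile, probs = probs[1])
  q_hi <- function(a) apply(a, c(1, 2), stats::quantile, probs = probs[2])
  make_tbl <- function(sal, lo, hi, block) {
    tibble::tibble(
      block = block,
      variable = rep(rownames(sal), times = ncol(sal)),
      lc = rep(seq_len(ncol(sal)), each = nrow(sal)),
      salience = as.vector(sal),
      boot_low = as.vector(lo),
      boot_high = as.vector(hi)
    )
  }
  out <- dplyr::bind_rows(
    make_tbl(fit$brain_saliences, q_lo(v_draws), q_hi(v_draws), "brain"),
    make_tbl(fit$behavior_saliences, q_lo(u_draws), q_hi(u_draws), "behavior")
  )
  dplyr::mutate(out, robust = .data$boot_low > 0 | .data$boot_high < 0)
}
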