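#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted outcome model
#'
#' One row per coefficient with estimate, standard error, test statistic and
#' p-value (Wald t for Gaussian fits, Wald z for logistic).
#'
#' @param x A `cap_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cap_fit <- function(x, ...) {
  coef_table(x)
}

#' @rdname tidy.cap_fit
#' @export
glance.cap_fit <- function(x, ...) {
  out <- tibble::tibble(
    family = x$family, n_obs = x$n_obs, converged = x$converged
  )
  if (!is.null(x$sigma2_subject)) {
    out$sigma2_subject <- x$sigma2_subject
    out$sigma2_residual <- x$sigma2_residual
    out$reml_criterion <- x$reml_criterion
  }
  if (!is.null(x$separation)) out$separation <- x$separation
  out
}

#' Tidy a PLSC decomposition
#'
#' One row per salience entry (brain and behavior blocks stacked), with the
#' latent component index and singular value.
#'
#' @param x A `plsc_fit`.
#' @param ... Unused.
#' @return A tibble (`block`, `variable`, `lc`, `salience`,
#'   `singular_value`).
#' @export
tidy.plsc_fit <- function(x, ...) {
  L <- length(x$singular_values)
  mk <- function(sal, block) {
    tibble::tibble(
      block = block,
      variable = rep(rownames(sal), times = L),
      lc = rep(seq_len(L), each = nrow(sal)),
      salience = as.vector(sal)
    )
  }
  out <- dplyr::bind_rows(
    mk(x$brain_saliences, "brain"),
    mk(x$behavior_saliences, "behavior")
  )
  out$singular_value <- x$singular_values[out$lc]
  out
}

#' @rdname tidy.plsc_fit
#' @export
glance.plsc_fit <- function(x, ...) {
  s2 <- x$singular_values^2
  lc_cor <- vapply(seq_along(s2), function(l) {
    stats::cor(x$latent_brain_scores[, l], x$latent_behavior_scores[, l])
  }, numeric(1))
  tibble::tibble(
    n_lc = length(s2),
    n_subjects = nrow(x$latent_brain_scores),
    n_groups = length(unique(x$groups)),
    explained_lc1 = s2[1] / sum(s2),
    latent_cor_lc1 = lc_cor[1]
  )
}

#' Tidy a consensus model-order report
#'
#' @param x A `consensus_report`.
#' @param ... Unused.
#' @return The per-order summary tibble (`k`, `pac`, `mean_consensus`).
#' @export
tidy.consensus_report <- function(x, ...) {
  x$summary
}
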