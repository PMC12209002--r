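#' Ordinary least squares fit
#'
#' OLS through R's QR-based fitter with coefficient t-tests on `n - p`
#' residual degrees of freedom. Rank-deficient designs are an error naming
#' the collinear columns rather than a silent drop.
#'
#' @param data Data frame holding the response and predictors.
#' @param formula Model formula.
#' @return An object of class `cap_fit` wrapping the `lm` fit.
#' @export
fit_linear <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s.",
      paste(aliased, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm(formula, data)
  new_cap_fit(fit, family = "gaussian", formula = formula)
}

#' Logistic regression fit
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`) with Wald z-tests plus per-term likelihood-ratio tests
#' (`p_lrt`): at small n the Wald statistic is non-monotone in the effect
#' (Hauck-Donner), so the LRT is the recommended basis for significance.
#' Complete or quasi-complete separation is detected (fitted probabilities
#' numerically 0/1) and reported through the `separation` flag instead of
#' silently diverging.
#'
#' @param data Data frame with a 0/1 (or logical) response.
#' @param formula Model formula.
#' @return A `cap_fit`; `$separation` is `TRUE` when separation occurred.
#' @export
fit_logistic <- function(data, formula) {
  resp <- stats::model.response(stats::model.frame(formula, data))
  resp_num <- as.numeric(resp)
  if (!all(resp_num %in% c(0, 1))) {
    stop("logistic response must be 0/1 or logical.", call. = FALSE)
  }
  if (length(unique(resp_num)) < 2) {
    stop("both response classes must be present.", call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  eps <- 1e-8
  p_hat <- stats::fitted(fit)
  if (all(p_hat < eps | p_hat > 1 - eps)) separation <- TRUE
  out <- new_cap_fit(fit, family = "binomial", formula = formula)
  out$separation <- separation
  lrt <- suppressWarnings(stats::drop1(fit, test = "LRT"))
  out$lrt <- stats::setNames(lrt[["Pr(>Chi)"]], rownames(lrt))
  if (separation) {
    warning("complete or quasi-complete separation detected; coefficients are unreliable.")
  }
  out
}

#' Random-intercept linear mixed model
#'
#' Gaussian random-intercept model fitted by REML (`lme4::lmer`), the
#' repeated-measures workhorse for a handful of timepoints per subject.
#' Fixed-effect inference is by Wald t-tests on residual degrees of freedom
#' (`n - p`), a documented approximation adequate at this design size. When
#' the between-subject variance is estimated at the boundary (zero) the
#' fixed effects coincide with OLS.
#'
#' @param data Data frame in long format.
#' @param formula Fixed-effects formula (response on the left).
#' @param subject Name of the subject identifier column.
#' @return A `cap_fit` with variance components `sigma2_subject`,
#'   `sigma2_residual`, and the REML criterion.
#' @export
fit_random_intercept <- function(data, formula, subject = "subject") {
  if (!subject %in% names(data)) {
    stop(sprintf("subject column '%s' not found.", subject), call. = FALSE)
  }
  if (!any(table(data[[subject]]) >= 2)) {
    stop("need at least one subject with >= 2 observations.", call. = FALSE)
  }
  full <- stats::as.formula(
    paste(paste(deparse(formula), collapse = " "), sprintf("+ (1 | %s)", subject)),
    env = environment(formula)
  )
  fit <- lme4::lmer(full, data = data, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- new_cap_fit(fit, family = "gaussian", formula = full)
  out$sigma2_subject <- vc$vcov[vc$grp == subject]
  out$sigma2_residual <- vc$vcov[vc$grp == "Residual"]
  out$reml_criterion <- as.numeric(stats::deviance(fit, REML = TRUE))
  out
}

# uniform wrapper so lm/glm/lmer fits tidy and print the same way
new_cap_fit <- function(fit, family, formula) {
  structure(
    list(fit = fit, family = family, formula = formula,
      n_obs = stats::nobs(fit), converged = fit_converged(fit)),
    class = "cap_fit"
  )
}

fit_converged <- function(fit) {
  if (inherits(fit, "glm")) return(fit$converged)
  if (inherits(fit, "lmerMod")) {
    return(length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0)
  }
  TRUE
}

#' @export
print.cap_fit <- function(x, ...) {
  cat(sprintf("<cap_fit> %s, n = %d\n", x$family, x$n_obs))
  print(coef_table(x))
  invisible(x)
}

# coefficient table with the package's df convention
coef_table <- function(x) {
  fit <- x$fit
  if (inherits(fit, "lmerMod")) {
    cf <- as.data.frame(stats::coef(summary(fit)))
    df <- x$n_obs - nrow(cf)
    tibble::tibble(
      term = rownames(cf), estimate = cf[, "Estimate"],
      std_error = cf[, "Std. Error"], statistic = cf[, "t value"],
      df = df, p = 2 * stats::pt(-abs(cf[, "t value"]), df)
    )
  } else {
    cf <- as.data.frame(stats::coef(summary(fit)))
    stat_col <- if (x$family == "binomial") "z value" else "t value"
    p_col <- if (x$family == "binomial") "Pr(>|z|)" else "Pr(>|t|)"
    out <- tibble::tibble(
      term = rownames(cf), estimate = cf[, "Estimate"],
      std_error = cf[, "Std. Error"], statistic = cf[, stat_col],
      df = if (x$family == "binomial") NA_real_ else fit$df.residual,
      p = cf[, p_col]
    )
    if (!is.null(x$lrt)) out$p_lrt <- unname(x$lrt[out$term])
    out
  }
}

# wide per-subject-session metrics of one CAP state, z-standardized columns
state_metrics_wide <- function(metrics, state, standardize = TRUE) {
  w <- metrics |>
    dplyr::filter(.data$state == !!state) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value",
      id_cols = c("subject", "session"))
  if (standardize) {
    for (col in setdiff(names(w), c("subject", "session"))) {
      if (stats::sd(w[[col]]) > 0) w[[col]] <- as.numeric(scale(w[[col]]))
    }
  }
  w
}

#' Run the outcome model suite (Models 1-5)
#'
#' Fits the prediction layer linking FPN-state dynamics to attentional and
#' executive scores. The term structures follow the study narrative and are
#' overridable via `formulas`:
#' * **Model 1** (mixed, per TMT score): score at pre/3m ~ deficit x session
#'   x betweenness + occurrence + resilience + (1 | subject) — attentive
#'   performance against deficit status, time and FPN state properties;
#' * **Model 2** (logistic): 1-week deficit ~ pre-surgical OUT-degree, and a
#'   companion fit on IN-degree (transition properties; the two degrees are
#'   near-duplicates by flow balance — a state is entered about as often as
#'   it is left — so they enter separate fits rather than one collinear
#'   design);
#' * **Model 3** (logistic): 1-week deficit ~ pre-surgical occurrence +
#'   resilience (stability properties);
#' * **Model 4** (linear, per score): 1-week score ~ pre-surgical IN-degree;
#' * **Model 5** (linear, per executive score): 3-month score ~ pre-surgical
#'   OUT-degree.
#'
#' Metric predictors are the designated FPN state's values, standardized so
#' coefficients are comparable across metrics. Scatter data for the
#' pre-surgical degree-vs-score panels are returned alongside.
#'
#' @param metrics Tidy metrics tibble ([cohort_metrics()]).
#' @param behavior Behavior tibble.
#' @param fpn_state CAP state index whose metrics enter the models.
#' @param tmt_scores Scores treated as attentive/executive responses.
#' @param models Which of models 1..5 to fit.
#' @return A list of class `model_suite`: `fits` (named list of `cap_fit`),
#'   `significance` (tidy coefficient table over all fits), `scatter_data`.
#' @export
run_model_suite <- function(metrics, behavior, fpn_state,
                            tmt_scores = c("TMTA", "TMTB", "TMTBA"),
                            models = 1:5) {
  flags <- classify_deficit(behavior, timepoint = "1w")
  mw <- state_metrics_wide(metrics, fpn_state)
  pre_m <- dplyr::filter(mw, .data$session == "pre")
  fits <- list()

  if (1 %in% models) {
    # behavior at pre / 3m matched to imaging sessions pre / post3m
    long <- behavior |>
      dplyr::filter(.data$timepoint %in% c("pre", "3m"),
        .data$score %in% tmt_scores) |>
      dplyr::mutate(session = ifelse(.data$timepoint == "pre", "pre", "post3m")) |>
      dplyr::left_join(flags[, c("subject", "deficit")], by = "subject") |>
      dplyr::left_join(mw, by = c("subject", "session"))
    for (sc in tmt_scores) {
      d <- dplyr::filter(long, .data$score == sc)
      fits[[paste0("model1_", sc)]] <- fit_random_intercept(
        d, value ~ deficit * session * betweenness + occurrence + resilience,
        subject = "subject"
      )
    }
  }
  pre_full <- dplyr::left_join(pre_m, flags[, c("subject", "deficit")],
    by = "subject")
  if (2 %in% models) {
    fits$model2_out <- fit_logistic(pre_full, deficit ~ out_degree)
    fits$model2_in <- fit_logistic(pre_full, deficit ~ in_degree)
  }
  if (3 %in% models) {
    fits$model3 <- fit_logistic(pre_full, deficit ~ occurrence + resilience)
  }
  score_at <- function(tp) {
    behavior |>
      dplyr::filter(.data$timepoint == tp, .data$score %in% tmt_scores) |>
      dplyr::select("subject", "score", "value")
  }
  if (4 %in% models) {
    d1w <- dplyr::left_join(score_at("1w"), pre_full, by = "subject")
    for (sc in tmt_scores) {
      fits[[paste0("model4_", sc)]] <- fit_linear(
        dplyr::filter(d1w, .data$score == sc),
        value ~ in_degree
      )
    }
  }
  if (5 %in% models) {
    d3m <- dplyr::left_join(score_at("3m"), pre_full, by = "subject")
    for (sc in tmt_scores) {
      fits[[paste0("model5_", sc)]] <- fit_linear(
        dplyr::filter(d3m, .data$score == sc),
        value ~ out_degree
      )
    }
  }
  significance <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(coef_table(f), model = nm, .before = 1)
  })
  scatter <- behavior |>
    dplyr::filter(.data$timepoint %in% c("pre", "1w", "3m")) |>
    dplyr::left_join(pre_full[, c("subject", "in_degree", "out_degree", "deficit")],
      by = "subject") |>
    dplyr::select("subject", "timepoint", "score", "value", "in_degree",
      "out_degree", "deficit")
  structure(
    list(fits = fits, significance = significance, scatter_data = scatter,
      fpn_state = fpn_state),
    class = "model_suite"
  )
}

#' @export
print.model_suite <- function(x, ...) {
  cat(sprintf("<model_suite> %d fitted models (FPN state %d)\n",
    length(x$fits), x$fpn_state))
  sig <- dplyr::filter(x$significance, .data$term != "(Intercept)", .data$p < 0.05)
  if (nrow(sig) > 0) {
    cat("significant terms (p < 0.05):\n")
    print(sig[, c("model", "term", "estimate", "p")], n = 20)
  } else {
    cat("no significant terms at p < 0.05\n")
  }
  invisible(x)
}
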