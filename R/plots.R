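#' Plot CAP spatial maps
#'
#' Heatmap of the `k x P` CAP maps: mean z-scored BOLD of the member frames,
#' positive = co-activation, negative = co-deactivation.
#'
#' @param object A `cap_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cap_set <- function(object, ...) {
  df <- tibble::tibble(
    cap = factor(rep(seq_len(object$k), times = ncol(object$maps))),
    parcel = rep(seq_len(ncol(object$maps)), each = object$k),
    value = as.vector(object$maps)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parcel, y = .data$cap,
    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
      high = "firebrick3", name = "mean z") +
    ggplot2::labs(x = "parcel", y = "CAP",
      title = "Co-activation pattern maps") +
    ggplot2::theme_minimal()
}

#' Plot the consensus model-order selection
#'
#' PAC (proportion of ambiguous clustering) across candidate model orders;
#' the selected order (minimum PAC) is highlighted.
#'
#' @param object A `consensus_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_report <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$pac)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = df[df$k == object$selected_k, ],
      color = "firebrick3", size = 3) +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "model order k", y = "PAC",
      title = sprintf("Consensus selection: k = %d", object$selected_k)) +
    ggplot2::theme_minimal()
}

#' Plot PLSC saliences with bootstrap intervals
#'
#' Bar plot of brain and behavior saliences for one latent component with
#' 5th-95th percentile bootstrap error bars; robust saliences (interval
#' excluding 0) are filled.
#'
#' @param boot Bootstrap tibble from [plsc_bootstrap()].
#' @param lc Latent component to display (default 1).
#' @return A ggplot object.
#' @export
plot_plsc_saliences <- function(boot, lc = 1) {
  df <- dplyr::filter(boot, .data$lc == !!lc)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$salience,
    alpha = .data$robust)) +
    ggplot2::geom_col(fill = "firebrick3") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$boot_low,
      ymax = .data$boot_high), width = 0.25, alpha = 1) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
      name = "robust") +
    ggplot2::facet_wrap(~block, scales = "free_x") +
    ggplot2::labs(x = NULL, y = sprintf("LC%d salience", lc),
      title = "PLSC saliences (bootstrap 5th-95th percentiles)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot pre-surgical FPN dynamics against scores by deficit group
#'
#' Scatter of pre-surgical IN-/OUT-degree of the FPN state against scores at
#' a chosen timepoint, colored by 1-week deficit status, with per-group
#' linear fits.
#'
#' @param suite A `model_suite` from [run_model_suite()].
#' @param timepoint Score timepoint to display (default `"1w"`).
#' @return A ggplot object.
#' @export
plot_degree_scatter <- function(suite, timepoint = "1w") {
  df <- suite$scatter_data |>
    dplyr::filter(.data$timepoint == !!timepoint) |>
    tidyr::pivot_longer(cols = c("in_degree", "out_degree"),
      names_to = "degree", values_to = "degree_value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree_value, y = .data$value,
    color = .data$deficit)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      linewidth = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "forestgreen",
      `TRUE` = "firebrick3"), name = "1w deficit") +
    ggplot2::facet_grid(score ~ degree, scales = "free") +
    ggplot2::labs(x = "pre-surgical degree (share of switches)",
      y = sprintf("score at %s", timepoint)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
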