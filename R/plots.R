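#' Plot per-cell rank(nTA)
#'
#' Cells ordered by nTA with the rank transform on the x axis — the
#' maximal-contrast view used for per-cell condensation scoring.
#'
#' @param cells Output of [per_cell_counts()].
#' @return A ggplot.
#' @export
plot_rank_nta <- function(cells) {
  df <- dplyr::filter(cells, !is.na(.data$rank_nta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_nta, y = .data$nta)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "rank(nTA)", y = "nTA",
                  title = "Per-cell normalized telomere abundance") +
    ggplot2::theme_minimal()
}

#' Plot the motif run-length histogram
#'
#' @param hist Output of [motif_run_histogram()].
#' @return A ggplot.
#' @export
plot_run_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = factor(.data$run_length),
                                     y = .data$n_reads)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "tandem motif copies (max per read)", y = "reads",
                  title = "Telomere motif run lengths") +
    ggplot2::theme_minimal()
}

#' Plot a per-base frequency matrix
#'
#' Line plot of base frequency by position — the numeric rendering of the
#' average motif of oriented telomere-like reads or of the sequence context
#' around Tn5 insertion points.
#'
#' @param object A `base_freq_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot base_freq_matrix
#' @export
autoplot.base_freq_matrix <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object)) |>
    dplyr::mutate(position = as.integer(rownames(object))) |>
    tidyr::pivot_longer(c("A", "C", "G", "T", "N"),
                        names_to = "base", values_to = "frequency")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$frequency,
                                   colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp)", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot telomere-motif proximity to insertion points
#'
#' @param hist Output of [telomere_proximity_histogram()].
#' @return A ggplot.
#' @export
plot_proximity_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$offset, y = .data$n)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "offset of nearest TTAGGG start from insertion (bp)",
                  y = "insertions",
                  title = "Telomere motif near Tn5 insertion points") +
    ggplot2::theme_minimal()
}

#' Plot the training trace of an origin model
#'
#' @param object A fitted `origin_model`.
#' @param ... Unused.
#' @return A ggplot of train/test MSE per epoch.
#' @method autoplot origin_model
#' @export
autoplot.origin_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("train_mse", "test_mse"),
                            names_to = "set", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "MSE of predicted log10(1 + distance)") +
    ggplot2::theme_minimal()
}

#' Plot a grouped correlation ranking
#'
#' Mean per-group correlation against its across-group variance, the view
#' that separates consistent correlates from G/C-content artifacts.
#'
#' @param object A `grouped_correlation`.
#' @param top Label the `top` features by `|mean_over_var|` (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grouped_correlation
#' @export
autoplot.grouped_correlation <- function(object, top = 10L, ...) {
  df <- object$by_feature
  lab <- utils::head(dplyr::arrange(df, dplyr::desc(abs(.data$mean_over_var))),
                     top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_rho, y = .data$var_rho)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$feature),
                       vjust = -0.6, size = 2.8) +
    ggplot2::labs(x = "mean per-group correlation with nTA",
                  y = "variance across groups") +
    ggplot2::theme_minimal()
}
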