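#' Plot an MDS embedding
#'
#' Scatter of the two-dimensional configuration; when a design is given,
#' points are colored by sequence and connected in order of position so
#' the within-sequence trajectories are visible.
#'
#' @param object An `embedding` from [nonmetric_mds()].
#' @param design Optional design table (points assumed in event order).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embedding <- function(object, design = NULL, ...) {
  df <- tidy.embedding(object)
  if (!is.null(design)) {
    design <- validate_design(design)
    df$sequence <- factor(design$sequence_id)
    df$position <- design$position
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                          color = .data$sequence)) +
      ggplot2::geom_path(ggplot2::aes(group = .data$sequence), alpha = 0.6) +
      ggplot2::geom_point(size = 3) +
      ggplot2::geom_text(ggplot2::aes(label = .data$position), color = "white",
                         size = 2.5)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
      ggplot2::geom_point(size = 3)
  }
  p +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "dimension 1", y = "dimension 2",
      title = sprintf("Non-metric MDS (stress-1 = %.3f)", object$stress)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-subject Z-values of an ROI model
#'
#' Dot plot of the per-subject permutation Z-values with the group mean
#' and its standard error.
#'
#' @param object A `roi_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roi_result <- function(object, ...) {
  df <- object$subject_z
  gl <- glance.roi_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$z)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "gray50") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, color = "black",
                          linewidth = 1) +
    ggplot2::labs(
      x = NULL, y = "permutation Z",
      title = sprintf("%s (%s pairs): t = %.2f, p = %.3g, d = %.2f",
                      gl$roi_id, gl$subset, gl$statistic, gl$p.value, gl$d)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a similarity or similarity-change matrix
#'
#' @param m A 20 x 20 matrix (diagonal may be `NA`).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_similarity_matrix <- function(m, title = "pattern similarity change") {
  m <- unclass(m)
  df <- expand.grid(event_i = seq_len(nrow(m)), event_j = seq_len(ncol(m)))
  df$value <- m[cbind(df$event_i, df$event_j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event_j, y = .data$event_i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "gray90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "event", y = "event", fill = "Fisher z",
                  title = title) +
    ggplot2::theme_minimal()
}
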