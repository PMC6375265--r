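#' Plot a stress profile
#'
#' Drag-stress index per segment, coloured by segment kind; segments flagged
#' by [classify_sites()] (if the profile has been classified) are outlined
#' and the threshold drawn as a dashed line.
#'
#' @param object A `stress_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stress_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$segment_id <- factor(df$segment_id, levels = df$segment_id)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$segment_id,
                                        y = .data$stress_index,
                                        fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "drag-stress index (force units / cm²)",
                  fill = "segment kind") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("threshold" %in% names(df)) {
    p <- p + ggplot2::geom_hline(yintercept = df$threshold[1],
                                 linetype = "dashed")
  }
  p
}

#' Plot a concordance report
#'
#' Plaque-thickness midpoint against the drag-stress index, prone sites
#' marked; plaque-free (NIL) sections are drawn at zero thickness with an
#' open symbol.
#'
#' @param object A `concordance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance_report <- function(object, ...) {
  df <- tibble::as_tibble(object$pairs)
  df$thickness_plot <- dplyr::coalesce(df$thickness_mid_mm, 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stress_index,
                                   y = .data$thickness_plot,
                                   colour = .data$prone,
                                   shape = .data$plaque_observed)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                na.value = 4) +
    ggplot2::labs(x = "drag-stress index (force units / cm²)",
                  y = "plaque-thickness midpoint (relative mm)",
                  colour = "flagged prone", shape = "plaque observed") +
    ggplot2::theme_minimal()
}

#' Plot a hinge-model fit
#'
#' The measured (stress, thickness-midpoint) points with the fitted hinge
#' curve `a * max(0, s0 - stress)` overlaid.
#'
#' @param object A `hinge_fit` from [recover_parameters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hinge_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(
    stress_index = seq(0, max(df$stress_index) * 1.05, length.out = 200)
  )
  grid$fit <- object$a * pmax(0, object$s0 - grid$stress_index)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stress_index,
                                   y = .data$thickness_mid_mm)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "drag-stress index (force units / cm²)",
                  y = "plaque-thickness midpoint (mm)") +
    ggplot2::theme_minimal()
}
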