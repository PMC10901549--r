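#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot class-average normalised decay curves
#'
#' Computes [average_decay_curve()] per phenotype and overlays the curves on
#' a log-scaled y axis, the standard way to compare metabolic groups:
#' glycolytic cells (higher free-NAD(P)H fraction) decay faster after the
#' peak.
#'
#' @param cells List of labelled `flim_cell` records sharing one time axis.
#' @return A ggplot object.
#' @export
plot_decay_curves <- function(cells) {
  phen <- vapply(cells, function(cl) cl$phenotype %||% "unlabeled", character(1))
  ax <- cells[[1]]$axis
  df <- purrr::map_dfr(unique(phen), function(p) {
    cv <- average_decay_curve(cells[phen == p])
    tibble::tibble(phenotype = p, time_ns = frame_time_ns(seq_along(cv), ax),
                   intensity = cv)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ns, .data$intensity,
                                   colour = .data$phenotype)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "normalised intensity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_decay_curves Intensity image of one cell (summed counts).
#' @param object A `flim_cell`.
#' @param ... Unused.
#' @export
autoplot.flim_cell <- function(object, ...) {
  tot <- apply(object$counts, c(1, 2), sum)
  df <- tidyr::expand_grid(x = seq_len(nrow(tot)), y = seq_len(ncol(tot)))
  df$photons <- as.vector(tot)
  ggplot2::ggplot(df, ggplot2::aes(.data$y, .data$x, fill = .data$photons)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("cell %s (%s)", object$cell_id,
                                  object$phenotype %||% "unlabeled")) +
    ggplot2::theme_void()
}

#' @describeIn plot_decay_curves Training/validation loss and accuracy by
#'   epoch for a trained model.
#' @export
autoplot.flim_cnn <- function(object, ...) {
  df <- tidy(object)
  df$kind <- ifelse(grepl("loss", df$metric), "loss", "accuracy")
  df$split <- ifelse(grepl("^val", df$metric), "validation", "training")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$kind, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_decay_curves ROC curve of a binary metrics report.
#' @export
autoplot.flim_metrics <- function(object, ...) {
  if (is.null(object$roc))
    stop("no ROC stored (multiclass or score-free report)", call. = FALSE)
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a mean-lifetime image
#'
#' @param taum Output of [tau_m_image()].
#' @return A ggplot object; background (unfitted) pixels are blank.
#' @export
plot_tau_m <- function(taum) {
  m <- taum$tau_m
  df <- tidyr::expand_grid(x = seq_len(nrow(m)), y = seq_len(ncol(m)))
  df$tau_m_ps <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$y, .data$x, fill = .data$tau_m_ps)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "tau_m (ps)") +
    ggplot2::theme_void()
}
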