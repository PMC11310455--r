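#' Plot a per-nucleotide probability track
#'
#' Binding probability along one sequence, with the true site span shaded
#' when labels are available.
#'
#' @param prediction prediction tibble from [predict.tfsnr_model()].
#' @param id sequence id to plot (default: first row).
#' @param threshold horizontal reference line.
#' @return A ggplot object.
#' @export
plot_nuc_probs <- function(prediction, id = prediction$id[1], threshold = 0.5) {
  row <- prediction[prediction$id == id, ]
  if (nrow(row) == 0) abort(sprintf("id '%s' not found", id))
  df <- tibble(position = seq_along(row$nuc_probs[[1]]),
               prob = row$nuc_probs[[1]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$prob))
  if ("nuc_labels" %in% names(row)) {
    lab <- row$nuc_labels[[1]]
    if (any(lab == 1L)) {
      runs <- rle(lab)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      spans <- tibble(xmin = starts[runs$values == 1L] - 0.5,
                      xmax = ends[runs$values == 1L] + 0.5)
      p <- p + ggplot2::geom_rect(
        data = spans,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = 0, ymax = 1),
        inherit.aes = FALSE, fill = "goldenrod", alpha = 0.25)
    }
  }
  p +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "position (bp)", y = "binding probability",
                  title = id) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a mean attention profile
#'
#' @param profile tibble from [aggregate_attention()].
#' @param site_span optional `c(start, end)` (1-based inclusive) to shade
#'   the known site region.
#' @return A ggplot object.
#' @export
plot_attention_profile <- function(profile, site_span = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$position, y = .data$mean_weight))
  if (!is.null(site_span)) {
    p <- p + ggplot2::annotate("rect", xmin = site_span[1] - 0.5,
                               xmax = site_span[2] + 0.5,
                               ymin = -Inf, ymax = Inf,
                               fill = "goldenrod", alpha = 0.25)
  }
  p +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "position (bp)", y = "mean attention received") +
    ggplot2::theme_minimal()
}

#' Heatmap of sequence-summary correlations
#'
#' @param object a `tfsnr_cls_cor` from [cls_correlation()].
#' @param ... unused.
#' @return A ggplot object (rows/columns in clustering order).
#' @export
autoplot.tfsnr_cls_cor <- function(object, ...) {
  ord <- object$order
  cm <- object$cor[ord, ord]
  df <- tidyr::expand_grid(row = seq_len(nrow(cm)), col = seq_len(ncol(cm)))
  df$value <- cm[as.matrix(df[, c("row", "col")])]
  df$row_id <- factor(rownames(cm)[df$row], levels = rev(rownames(cm)))
  df$col_id <- factor(colnames(cm)[df$col], levels = colnames(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col_id, y = .data$row_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Pearson r") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Simple motif logo
#'
#' Letter heights proportional to per-position information content times
#' base frequency (bits), the conventional sequence-logo scaling.
#'
#' @param object a `tfsnr_pwm` from [build_pwm()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tfsnr_pwm <- function(object, ...) {
  m <- unclass(object)
  w <- ncol(m)
  eps <- 1e-9
  ic <- vapply(seq_len(w), function(j) {
    2 + sum(m[, j] * log2(m[, j] + eps))
  }, 0)
  rows <- list()
  for (j in seq_len(w)) {
    h <- m[, j] * ic[j]
    ord <- order(h)
    y0 <- 0
    for (b in ord) {
      rows[[length(rows) + 1]] <- tibble(
        position = j, base = rownames(m)[b], y = y0 + h[b] / 2, height = h[b])
      y0 <- y0 + h[b]
    }
  }
  df <- dplyr::bind_rows(rows)
  df <- df[df$height > 0.01, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$y,
                                   label = .data$base, colour = .data$base,
                                   size = .data$height)) +
    ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 10)) +
    ggplot2::scale_colour_manual(values = c(A = "#109648", C = "#255C99",
                                            G = "#F7B32B", T = "#D62839")) +
    ggplot2::scale_x_continuous(breaks = seq_len(w)) +
    ggplot2::labs(x = "position", y = "information (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Training-history curve
#'
#' @param object a fitted `tfsnr_model`.
#' @param ... unused.
#' @return A ggplot object of train/validation loss per epoch.
#' @export
autoplot.tfsnr_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::labs(x = "epoch", y = "multi-task loss", colour = NULL) +
    ggplot2::theme_minimal()
}
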