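#' Tidy a fitted model's training history
#'
#' @param x a fitted `tfsnr_model`.
#' @param ... unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `best` (logical, the retained epoch).
#' @export
tidy.tfsnr_model <- function(x, ...) {
  dplyr::mutate(x$history, best = .data$epoch == x$best_epoch)
}

#' One-row model summary
#'
#' @param x a fitted `tfsnr_model`.
#' @param ... unused.
#' @return One-row tibble: architecture fields, parameter count, epochs
#'   run, best epoch and best validation loss.
#' @export
glance.tfsnr_model <- function(x, ...) {
  tibble(
    k = x$config$k,
    n_layers = x$config$n_layers,
    n_heads = x$config$n_heads,
    d_model = x$config$d_model,
    lambda = x$config$lambda_weight,
    n_params = x$n_params,
    epochs_run = if (nrow(x$history)) max(x$history$epoch) else 0L,
    best_epoch = x$best_epoch,
    best_val_loss = if (nrow(x$history)) min(x$history$val_loss) else NA_real_
  )
}
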