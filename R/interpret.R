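#' Pairwise correlation of sequence-summary vectors
#'
#' Extracts the final-layer `[CLS]` hidden vector of every sequence — the
#' representation the sequence-level head reads — and computes the Pearson
#' correlation between every pair. Rows are ordered by average-linkage
#' hierarchical clustering on `1 - correlation`, the order used by the
#' heatmap. In a well-trained model, sequences of the same class correlate
#' more strongly with each other than across classes.
#'
#' @param model fitted `tfsnr_model`.
#' @param sequences labeled dataset with at least 2 rows.
#' @param batch_size forward-pass batch size.
#' @return Object of class `tfsnr_cls_cor`: list with `cor` (symmetric
#'   matrix, unit diagonal), `order` (clustering leaf order), `seq_label`.
#' @export
cls_correlation <- function(model, sequences, batch_size = 64L) {
  validate_dataset(sequences)
  if (nrow(sequences) < 2) abort("need at least 2 sequences")
  enc <- encode_dataset(sequences, model$vocab)
  n <- nrow(enc$input_ids)
  cls <- matrix(0, n, model$config$d_model)
  for (idx in batch_indices(n, batch_size)) {
    fw <- transformer_forward(model$weights, model$config,
                              enc$input_ids[idx, , drop = FALSE],
                              enc$attention_mask[idx, , drop = FALSE])
    cls[idx, ] <- fw$cls
  }
  sds <- apply(cls, 1, stats::sd)
  if (any(sds == 0)) {
    abort("correlation undefined: constant summary vector encountered")
  }
  cm <- cor(t(cls))
  dimnames(cm) <- list(sequences$id, sequences$id)
  ord <- hclust(as.dist(1 - cm), method = "average")$order
  structure(
    list(cor = cm, order = ord, seq_label = sequences$seq_label),
    class = "tfsnr_cls_cor"
  )
}

#' @export
print.tfsnr_cls_cor <- function(x, ...) {
  cat(sprintf("<tfsnr_cls_cor> %d x %d sequence-summary correlation matrix\n",
              nrow(x$cor), ncol(x$cor)))
  invisible(x)
}

#' Mean per-position attention profile over a dataset
#'
#' For each sequence, the attention *received* by every token slot is taken
#' as the column mass of the row-stochastic attention map (how much all
#' queries attend to that key), averaged over heads. Token-slot mass is
#' mapped to nucleotides by averaging over the k-mers covering each position,
#' then averaged over all sequences. With sites planted at a fixed position,
#' a trained model's profile peaks over the site span.
#'
#' @param model fitted `tfsnr_model`.
#' @param dataset labeled dataset; all sequences must have equal length.
#' @param layer encoder layer to aggregate (default: last).
#' @param batch_size forward-pass batch size.
#' @return Tibble with columns `position` (1-based) and `mean_weight`.
#' @export
aggregate_attention <- function(model, dataset, layer = model$config$n_layers,
                                batch_size = 32L) {
  validate_dataset(dataset)
  L <- unique(nchar(dataset$seq))
  if (length(L) != 1) abort("all sequences must have the same length")
  if (layer < 1 || layer > model$config$n_layers) abort("invalid layer")
  k <- model$vocab$k
  enc <- encode_dataset(dataset, model$vocab)
  n <- nrow(enc$input_ids)
  n_kmers <- L - k + 1L
  acc <- numeric(L)
  # token i covers nucleotides i..i+k-1; coverage count per position
  cover <- pmin(seq_len(L), k, n_kmers, L - seq_len(L) + 1L)
  for (idx in batch_indices(n, batch_size)) {
    fw <- transformer_forward(model$weights, model$config,
                              enc$input_ids[idx, , drop = FALSE],
                              enc$attention_mask[idx, , drop = FALSE],
                              collect_attention = TRUE)
    A <- fw$attention[[layer]]                # B x H x T x T
    for (j in seq_along(idx)) {
      # column mass averaged over heads
      slot_mass <- apply(A[j, , , , drop = FALSE], 4, sum) / dim(A)[2]
      tok_mass <- slot_mass[2:(n_kmers + 1L)]  # k-mer slots only
      nuc <- numeric(L)
      for (i in seq_len(n_kmers)) {
        span <- i:(i + k - 1L)
        nuc[span] <- nuc[span] + tok_mass[i]
      }
      acc <- acc + nuc / cover
    }
  }
  tibble(position = seq_len(L), mean_weight = acc / n)
}
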