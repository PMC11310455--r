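#' Fit the multi-task k-mer transformer
#'
#' Trains the encoder plus both prediction heads with Adam on the multi-task
#' objective `lambda * BCE(sequence) + (1 - lambda) * BCE(token)`. A
#' validation subset (pair-aware, so a positive and its shuffled twin stay
#' together) is carved out of the training data; after every epoch the
#' validation loss is evaluated, the best-so-far weights are retained, and
#' training stops early once the validation loss has failed to improve for
#' `patience` consecutive epochs. Fully deterministic for a fixed seed.
#'
#' @param data labeled training dataset (see [make_dataset()]).
#' @param config a [model_config()].
#' @param epochs maximum number of epochs (default 10). `epochs = 0` returns
#'   the untrained, randomly initialized model (useful as a chance-level
#'   baseline).
#' @param patience early-stopping patience in epochs (default 2).
#' @param batch_size sequences per optimization step.
#' @param lr Adam learning rate.
#' @param warmup_steps linear learning-rate warmup steps.
#' @param clip_norm global gradient-norm cap (default 1.0; `Inf` disables
#'   clipping).
#' @param weight_decay decoupled (AdamW-style) weight decay applied to
#'   weight matrices (default 0.01).
#' @param lr_schedule `"linear"` (default): after warmup the learning rate
#'   decays linearly to zero over the scheduled `epochs`; `"constant"` holds
#'   it fixed after warmup.
#' @param val_frac fraction of pairs held out for early stopping.
#' @param seed integer seed driving data order, dropout and validation split.
#' @param verbose print per-epoch losses.
#' @return Object of class `tfsnr_model`: list with `weights` (best
#'   validation loss), `config`, `vocab`, `history` (tibble of per-epoch
#'   train/validation losses), `best_epoch`, `n_params`.
#' @seealso [predict.tfsnr_model()], [evaluate()], [tidy.tfsnr_model()]
#' @export
tfsnr_fit <- function(data, config = model_config(), epochs = 10L,
                      patience = 2L, batch_size = 16L, lr = 1e-3,
                      warmup_steps = 50L, clip_norm = 1.0, weight_decay = 0.01,
                      lr_schedule = c("linear", "constant"),
                      val_frac = 0.1, seed = 1L, verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  validate_dataset(data)
  if (nrow(data) == 0) abort("cannot train on an empty dataset")
  vocab <- build_vocab(config$k)
  weights <- init_weights(config, length(vocab$tokens))

  if (epochs == 0L) {
    return(new_tfsnr_model(weights, config, vocab,
                           history = tibble(epoch = integer(0),
                                            train_loss = numeric(0),
                                            val_loss = numeric(0)),
                           best_epoch = 0L))
  }

  # pair-aware validation carve-out for early stopping
  n_pairs <- length(unique(if ("pair_id" %in% names(data)) data$pair_id else data$id))
  if (val_frac > 0 && n_pairs >= 4) {
    sp <- split_dataset(data, train_frac = 1 - val_frac,
                        seed = substream_seed(seed, "val_split"))
    train_data <- sp$train
    val_data <- sp$test
  } else {
    train_data <- data
    val_data <- data
  }

  enc <- encode_dataset(train_data, vocab)
  enc_val <- encode_dataset(val_data, vocab)
  n <- nrow(enc$input_ids)

  take <- function(e, idx) {
    list(input_ids = e$input_ids[idx, , drop = FALSE],
         token_labels = e$token_labels[idx, , drop = FALSE],
         attention_mask = e$attention_mask[idx, , drop = FALSE],
         seq_label = e$seq_label[idx])
  }
  val_loss_of <- function(w) {
    tot <- 0
    nb <- 0
    for (idx in batch_indices(nrow(enc_val$input_ids), batch_size)) {
      tot <- tot + loss_and_grads(w, config, take(enc_val, idx),
                                  want_grads = FALSE)$loss * length(idx)
      nb <- nb + length(idx)
    }
    tot / nb
  }

  total_steps <- epochs * length(batch_indices(n, batch_size))
  run <- function() {
    state <- adam_init(weights)
    step_no <- 0L
    skip <- if (config$position_embedding == "sinusoidal") "emb.pos" else character(0)
    history <- tibble(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
    best <- list(loss = Inf, weights = weights, epoch = 0L)
    stall <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (idx in batch_indices(n, batch_size, order = ord)) {
        lg <- loss_and_grads(weights, config, take(enc, idx),
                             dropout_active = config$dropout > 0)
        grads <- if (is.finite(clip_norm)) {
          clip_global_norm(lg$grads, clip_norm)
        } else lg$grads
        step_no <- step_no + 1L
        lr_now <- if (lr_schedule == "linear" && total_steps > warmup_steps) {
          lr * max(0, (total_steps - step_no) /
                     max(1L, total_steps - warmup_steps))
        } else lr
        upd <- adam_step(state, weights, grads, lr = lr_now,
                         warmup_steps = warmup_steps,
                         weight_decay = weight_decay, skip = skip)
        state <- upd$state
        weights <- upd$weights
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      vl <- val_loss_of(weights)
      history <- dplyr::bind_rows(history, tibble(
        epoch = ep, train_loss = ep_loss / n, val_loss = vl))
      if (verbose) {
        inform(sprintf("epoch %d: train %.4f, val %.4f", ep, ep_loss / n, vl))
      }
      if (vl < best$loss) {
        best <- list(loss = vl, weights = weights, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    list(history = history, best = best)
  }
  res <- withr::with_seed(substream_seed(seed, "train"), run())
  new_tfsnr_model(res$best$weights, config, vocab,
                  history = res$history, best_epoch = res$best$epoch)
}

new_tfsnr_model <- function(weights, config, vocab, history, best_epoch) {
  structure(
    list(weights = weights, config = config, vocab = vocab,
         history = history, best_epoch = best_epoch,
         n_params = n_parameters(weights)),
    class = "tfsnr_model"
  )
}

batch_indices <- function(n, batch_size, order = seq_len(n)) {
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) order[s:min(s + batch_size - 1L, n)])
}

#' @export
print.tfsnr_model <- function(x, ...) {
  cat(sprintf("<tfsnr_model> %d parameters | k=%d, %d layers x %d heads, d_model=%d\n",
              x$n_params, x$config$k, x$config$n_layers, x$config$n_heads,
              x$config$d_model))
  if (nrow(x$history) > 0) {
    cat(sprintf("  trained %d epoch(s); best validation loss %.4f at epoch %d\n",
                max(x$history$epoch), min(x$history$val_loss), x$best_epoch))
  } else {
    cat("  untrained (randomly initialized)\n")
  }
  invisible(x)
}

#' Predict binding probabilities
#'
#' Runs the fitted model over a dataset and returns, per sequence, the
#' sequence-level binding probability, the per-token probabilities, and the
#' per-nucleotide probabilities obtained by max-expansion
#' ([expand_token_probs()]).
#'
#' @param object fitted `tfsnr_model`.
#' @param newdata labeled dataset tibble (labels are carried through when
#'   present but not required: a tibble with `id` and `seq` suffices).
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return Tibble with columns `id`, `seq`, `seq_prob`, `token_probs`
#'   (list), `nuc_probs` (list), plus `seq_label`/`nuc_labels` when present
#'   in `newdata`.
#' @export
predict.tfsnr_model <- function(object, newdata, batch_size = 64L, ...) {
  had_labels <- "nuc_labels" %in% names(newdata)
  if (!had_labels) {
    newdata <- labeled_sequences(newdata$id, newdata$seq,
                                 lapply(nchar(newdata$seq), integer))
  }
  enc <- encode_dataset(newdata, object$vocab)
  n <- nrow(enc$input_ids)
  seq_prob <- numeric(n)
  token_probs <- vector("list", n)
  for (idx in batch_indices(n, batch_size)) {
    fw <- transformer_forward(object$weights, object$config,
                              enc$input_ids[idx, , drop = FALSE],
                              enc$attention_mask[idx, , drop = FALSE])
    seq_prob[idx] <- sigmoid(fw$seq_logits)
    p_tok <- sigmoid(fw$token_logits)
    for (j in seq_along(idx)) {
      n_kmers <- enc$L[idx[j]] - enc$k + 1L
      token_probs[[idx[j]]] <- p_tok[j, 2:(n_kmers + 1L)]
    }
  }
  out <- tibble(
    id = newdata$id, seq = newdata$seq, seq_prob = seq_prob,
    token_probs = token_probs,
    nuc_probs = purrr::pmap(list(token_probs, enc$L),
                            function(tp, L) expand_token_probs(tp, enc$k, L))
  )
  if (had_labels) {
    out$seq_label <- newdata$seq_label
    out$nuc_labels <- newdata$nuc_labels
  }
  out
}

#' Per-layer attention maps for a single sequence
#'
#' @param model fitted `tfsnr_model`.
#' @param labeled_seq one-row dataset (or list with `seq`, `nuc_labels`).
#' @return List of `n_layers` arrays, each `n_heads x T x T` row-stochastic
#'   over unmasked slots.
#' @export
attention_maps <- function(model, labeled_seq) {
  enc <- encode_dataset(labeled_seq[1, , drop = FALSE], model$vocab)
  fw <- transformer_forward(model$weights, model$config, enc$input_ids,
                            enc$attention_mask, collect_attention = TRUE)
  lapply(fw$attention, function(a) {
    # drop the batch dimension
    array(a[1, , , ], dim(a)[-1])
  })
}

#' Five-fold cross-validation over a hyperparameter grid
#'
#' Pairs (a positive and its shuffled twin) are partitioned into `folds`
#' folds; each candidate configuration is trained on `folds - 1` folds and
#' scored on the held-out fold. The candidate with the highest mean
#' validation nucleotide-level AUPR wins. The test set should be split off
#' *before* calling this, so it never influences selection.
#'
#' @param data labeled training dataset.
#' @param candidates list of candidate argument lists; each may contain
#'   [model_config()] arguments and/or the [tfsnr_fit()] arguments `epochs`,
#'   `lr`, `batch_size`, `patience`.
#' @param folds number of folds (default 5).
#' @param seed integer seed for fold assignment and training.
#' @param verbose print progress.
#' @return List with `best` (the winning candidate list), `best_index`,
#'   `results` (tibble: candidate, fold, auc, aupr) and `folds` (named
#'   vector mapping each pair id to its fold).
#' @export
cross_validate <- function(data, candidates, folds = 5L, seed = 1L,
                           verbose = FALSE) {
  validate_dataset(data)
  if (length(candidates) == 0) abort("candidate grid is empty")
  pid <- if ("pair_id" %in% names(data)) data$pair_id else data$id
  pairs <- unique(pid)
  if (folds > length(pairs)) abort("more folds than pairs")
  fold_of <- withr::with_seed(
    substream_seed(seed, "cv_folds"),
    setNames(sample(rep_len(seq_len(folds), length(pairs))), pairs)
  )
  fit_args <- c("epochs", "lr", "batch_size", "patience")
  results <- list()
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    cfg <- do.call(model_config, cand[setdiff(names(cand), fit_args)])
    for (f in seq_len(folds)) {
      tr <- data[fold_of[pid] != f, , drop = FALSE]
      te <- data[fold_of[pid] == f, , drop = FALSE]
      fit <- do.call(tfsnr_fit, c(
        list(data = tr, config = cfg, seed = substream_seed(seed, paste0("cv", ci, "_", f)),
             verbose = FALSE),
        cand[intersect(names(cand), fit_args)]
      ))
      met <- evaluate(fit, te)
      nuc <- met[met$level == "nucleotide", ]
      results[[length(results) + 1]] <- tibble(
        candidate = ci, fold = f, auc = nuc$auc, aupr = nuc$aupr)
      if (verbose) {
        inform(sprintf("candidate %d fold %d: AUPR %.3f", ci, f, nuc$aupr))
      }
    }
  }
  results <- dplyr::bind_rows(results)
  mean_aupr <- results |>
    dplyr::group_by(.data$candidate) |>
    dplyr::summarise(aupr = mean(.data$aupr, na.rm = TRUE))
  best_index <- mean_aupr$candidate[which.max(mean_aupr$aupr)]
  list(best = candidates[[best_index]], best_index = best_index,
       results = results, folds = fold_of)
}
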