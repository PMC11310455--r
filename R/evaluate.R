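#' Rank-based AUC and AUPR
#'
#' `auc_score()` is the Mann-Whitney rank statistic (ties handled by average
#' ranks), the probability that a random positive outranks a random
#' negative. `aupr_score()` is average precision: the precision-recall curve
#' is traversed from the highest score down, tied scores are processed as a
#' single group, and precision is accumulated per recovered positive. Both
#' return `NA` (with a warning) when the ground truth is single-class, rather
#' than a silently meaningless 0.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 ground truth.
#' @return Scalar in `[0, 1]`, or `NA` if undefined.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined: ground truth is single-class")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname auc_score
#' @export
aupr_score <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || all(labels == 1)) {
    warn("AUPR undefined: ground truth is single-class")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores so precision is evaluated once per threshold
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  tp <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp / n_cum
  sum(prec * tp_g) / n1
}

#' Threshold metrics from scores and labels
#'
#' Confusion-matrix metrics at an operating threshold plus the
#' threshold-free AUC/AUPR, as one tibble row.
#'
#' @param scores numeric prediction scores in `[0, 1]`.
#' @param labels 0/1 ground truth.
#' @param threshold operating threshold (score >= threshold is called
#'   positive).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `aupr`, `tp`, `fp`, `tn`, `fn`.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels == 1)
  fp <- sum(call_pos & labels == 0)
  tn <- sum(!call_pos & labels == 0)
  fn <- sum(!call_pos & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  single <- length(unique(labels)) < 2
  tibble(
    accuracy = (tp + tn) / length(labels),
    precision = precision, recall = recall, f1 = f1,
    auc = if (single) NA_real_ else auc_score(scores, labels),
    aupr = if (single) NA_real_ else aupr_score(scores, labels),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Evaluate a fitted model at both resolution levels
#'
#' Nucleotide-level metrics pool every position of every sequence
#' (micro-averaging) and score the max-expanded per-nucleotide
#' probabilities; sequence-level metrics use the `[CLS]`-head probability.
#' Micro pooling reflects the heavily imbalanced per-position task (about
#' 15 background positions per binding position in 100-bp windows).
#'
#' @param model fitted `tfsnr_model` (or a prediction tibble from
#'   [predict.tfsnr_model()] carrying labels).
#' @param test_set labeled dataset; ignored when `model` is already a
#'   prediction tibble.
#' @param threshold operating threshold in (0, 1).
#' @param average `"micro"` (pool positions, default) or `"macro"`
#'   (per-sequence metrics averaged) for the nucleotide level.
#' @return Tibble with two rows (`level` = "nucleotide", "sequence") of
#'   [binary_metrics()] columns.
#' @export
evaluate <- function(model, test_set = NULL, threshold = 0.5,
                     average = c("micro", "macro")) {
  average <- match.arg(average)
  pred <- if (inherits(model, "tfsnr_model")) {
    predict(model, test_set)
  } else {
    model
  }
  if (!"nuc_labels" %in% names(pred)) {
    abort("evaluation needs ground-truth labels in the test set")
  }
  nuc <- if (average == "micro") {
    binary_metrics(unlist(pred$nuc_probs), unlist(pred$nuc_labels), threshold)
  } else {
    per_seq <- purrr::map2(pred$nuc_probs, pred$nuc_labels,
                           function(p, y) {
                             if (length(unique(y)) < 2) return(NULL)
                             binary_metrics(p, y, threshold)
                           })
    dplyr::summarise_all(dplyr::bind_rows(per_seq), mean, na.rm = TRUE)
  }
  seq_m <- binary_metrics(pred$seq_prob, pred$seq_label, threshold)
  dplyr::bind_rows(
    dplyr::mutate(nuc, level = "nucleotide", .before = 1),
    dplyr::mutate(seq_m, level = "sequence", .before = 1)
  )
}

#' Cross-factor transfer matrix
#'
#' Evaluates each factor-specific model on each factor's held-out test set:
#' cell (A, B) holds the AUC/AUPR of the model trained on factor A scored on
#' the test set of factor B. Diagonal cells are ordinary self-evaluation.
#' Factors sharing a binding motif (e.g. members of one TF family) are
#' expected to transfer — off-diagonal scores near the diagonal — while
#' disjoint motifs are not. Missing model/test combinations yield NA rows.
#'
#' @param models named list of fitted `tfsnr_model`s, one per factor.
#' @param test_sets named list of labeled test datasets, one per factor.
#' @param level `"nucleotide"` (default) or `"sequence"`.
#' @param threshold operating threshold passed to [evaluate()].
#' @return Tibble with columns `train_tf`, `test_tf`, `auc`, `aupr` — long
#'   form of the square matrix over the union of factor names; use
#'   [tidyr::pivot_wider()] for the matrix layout.
#' @export
cross_tf_matrix <- function(models, test_sets, level = c("nucleotide", "sequence"),
                            threshold = 0.5) {
  level <- match.arg(level)
  tfs <- union(names(models), names(test_sets))
  if (length(tfs) == 0) abort("models and test_sets must be named lists")
  grid <- tidyr::expand_grid(train_tf = tfs, test_tf = tfs)
  res <- purrr::pmap(grid, function(train_tf, test_tf) {
    if (is.null(models[[train_tf]]) || is.null(test_sets[[test_tf]])) {
      return(tibble(auc = NA_real_, aupr = NA_real_))
    }
    m <- evaluate(models[[train_tf]], test_sets[[test_tf]], threshold)
    m <- m[m$level == level, ]
    tibble(auc = m$auc, aupr = m$aupr)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}
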