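test_that("early stopping halts after `patience` non-improving epochs", {
  pos <- generate_synthetic(synthetic_spec(20, motif = "CAGCTG", seed = 71))
  ds <- make_dataset(pos, seed = 72)
  # lr = 0 freezes the weights, so validation loss can never improve after
  # epoch 1; with patience 2 training must stop by epoch 3
  fit <- tfsnr_fit(ds, model_config(n_layers = 1L, d_model = 16L, n_heads = 2L,
                                    dropout = 0),
                   epochs = 10, patience = 2, lr = 0, batch_size = 8, seed = 73)
  expect_lte(max(fit$history$epoch), 3)
  expect_equal(fit$best_epoch, 1)
})

test_that("training reduces the loss on a strongly planted motif", {
  pos <- generate_synthetic(synthetic_spec(100, motif = "CAGCTG", seed = 74))
  ds <- make_dataset(pos, seed = 75)
  fit <- tfsnr_fit(ds, model_config(n_layers = 1L, d_model = 32L, n_heads = 4L),
                   epochs = 3, patience = 3, batch_size = 16, seed = 76)
  expect_lt(dplyr::last(fit$history$train_loss), fit$history$train_loss[1])
})

test_that("training is deterministic under a fixed seed", {
  pos <- generate_synthetic(synthetic_spec(12, motif = "CAGCTG", seed = 77))
  ds <- make_dataset(pos, seed = 78)
  cfg <- model_config(n_layers = 1L, d_model = 16L, n_heads = 2L)
  f1 <- tfsnr_fit(ds, cfg, epochs = 2, batch_size = 8, seed = 79)
  f2 <- tfsnr_fit(ds, cfg, epochs = 2, batch_size = 8, seed = 79)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("training errors on an empty dataset", {
  pos <- generate_synthetic(synthetic_spec(0, motif = "CAGCTG", seed = 1))
  expect_error(tfsnr_fit(make_dataset(pos), model_config()), "empty dataset")
})

test_that("cross-validation partitions pairs evenly and keeps twins together", {
  pos <- generate_synthetic(synthetic_spec(100, motif = "CAGCTG", seed = 80))
  ds <- make_dataset(pos, seed = 81)
  cv <- cross_validate(ds, list(list(epochs = 0, n_layers = 1L,
                                     d_model = 16L, n_heads = 2L)),
                       folds = 5, seed = 82)
  expect_equal(nrow(cv$results), 5)
  expect_equal(cv$best_index, 1)
  # fold sizes: 100 pairs over 5 folds
  expect_equal(as.integer(table(cv$folds)), rep(20L, 5))
  # hygiene: each pair sits in exactly one fold
  expect_setequal(names(cv$folds), unique(ds$pair_id))
})

test_that("cross-validation prefers a trained model over an untrained one", {
  pos <- generate_synthetic(synthetic_spec(60, motif = "CAGCTG", seed = 83))
  ds <- make_dataset(pos, seed = 84)
  cands <- list(
    list(epochs = 0, n_layers = 1L, d_model = 32L, n_heads = 4L),
    list(epochs = 3, n_layers = 1L, d_model = 32L, n_heads = 4L)
  )
  cv <- cross_validate(ds, cands, folds = 3, seed = 85)
  expect_equal(cv$best_index, 2)
  expect_error(cross_validate(ds, list(), folds = 3), "empty")
})

test_that("threshold metrics match a hand-computed confusion matrix", {
  # fixed 20-item toy: scores above/below 0.5 chosen so the confusion matrix
  # is TP=6, FP=2, TN=8, FN=4 by construction
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 6), rep(0.1, 4), rep(0.8, 2), rep(0.2, 8))
  m <- binary_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$tp, 6)
  expect_equal(m$fp, 2)
  expect_equal(m$tn, 8)
  expect_equal(m$fn, 4)
  expect_equal(m$accuracy, 14 / 20)
  expect_equal(m$precision, 6 / 8)
  expect_equal(m$recall, 6 / 10)
  expect_equal(m$f1, 2 * (6 / 8) * (6 / 10) / (6 / 8 + 6 / 10))
  # rank-based AUC, hand-derived: of the 100 positive/negative pairs only the
  # six 0.9-scored positives outrank negatives (60 wins, no ties) -> 0.60
  expect_equal(m$auc, 0.60)
  # average precision, hand-derived over thresholds 0.9 > 0.8 > 0.2 > 0.1:
  # 6 positives recovered at precision 6/6, the last 4 at precision 10/20
  expect_equal(m$aupr, (6 * (6 / 6) + 0 + 0 + 4 * (10 / 20)) / 10)
})

test_that("perfect predictions yield perfect metrics", {
  labels <- c(1, 1, 0, 0, 1, 0)
  m <- binary_metrics(c(0.9, 0.8, 0.1, 0.2, 0.95, 0.3), labels)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$auc, 1)
  expect_equal(m$aupr, 1)
})

test_that("all-positive calls at 15:1 imbalance give precision 1/16", {
  labels <- rep(c(1, rep(0, 15)), 40)     # 640 positions, 1:15
  scores <- rep(0.99, length(labels))
  m <- binary_metrics(scores, labels)
  expect_equal(m$precision, 1 / 16)
  expect_equal(m$recall, 1)
})

test_that("random scores give AUPR near prevalence and AUC near 1/2", {
  withr::local_seed(86)
  labels <- rep(c(1, rep(0, 15)), 625)    # 10,000 positions at 1:15
  scores <- runif(length(labels))
  expect_lt(abs(aupr_score(scores, labels) - 1 / 16), 0.02)
  expect_lt(abs(auc_score(scores, labels) - 0.5), 0.03)
})

test_that("rank-based AUC and AUPR agree with independent implementations", {
  withr::local_seed(87)
  labels <- c(rep(1, 30), rep(0, 70))
  scores <- c(rnorm(30, 1), rnorm(70))
  expect_equal(auc_score(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
  expect_equal(aupr_score(scores, labels), oracle_aupr(scores, labels))
  # with heavy score ties
  scores_t <- round(scores, 1)
  expect_equal(auc_score(scores_t, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores_t, quiet = TRUE))))
  expect_equal(aupr_score(scores_t, labels), oracle_aupr(scores_t, labels))
})

test_that("single-class ground truth yields NA metrics, not zero", {
  expect_warning(a <- auc_score(c(0.1, 0.9), c(1, 1)), "single-class")
  expect_true(is.na(a))
  expect_warning(p <- aupr_score(c(0.1, 0.9), c(0, 0)), "single-class")
  expect_true(is.na(p))
})

test_that("evaluate pools nucleotide positions and scores both levels", {
  pos <- generate_synthetic(synthetic_spec(6, motif = "CAGCTG", seed = 88))
  ds <- make_dataset(pos, seed = 89)
  fit <- tfsnr_fit(ds, model_config(n_layers = 1L, d_model = 16L, n_heads = 2L),
                   epochs = 0, seed = 90)
  m <- evaluate(fit, ds)
  expect_equal(m$level, c("nucleotide", "sequence"))
  expect_equal(m$tp[1] + m$fp[1] + m$tn[1] + m$fn[1], 12 * 100)
  expect_equal(m$tp[2] + m$fp[2] + m$tn[2] + m$fn[2], 12)
  mm <- evaluate(fit, ds, average = "macro")
  expect_equal(mm$level[1], "nucleotide")
})

test_that("a 1x1 cross-factor matrix equals plain evaluation", {
  pos <- generate_synthetic(synthetic_spec(6, motif = "CAGCTG", seed = 91))
  ds <- make_dataset(pos, seed = 92)
  fit <- tfsnr_fit(ds, model_config(n_layers = 1L, d_model = 16L, n_heads = 2L),
                   epochs = 0, seed = 93)
  mat <- cross_tf_matrix(list(A = fit), list(A = ds))
  expect_equal(nrow(mat), 1)
  ref <- evaluate(fit, ds)
  expect_equal(mat$auc, ref$auc[ref$level == "nucleotide"])
  expect_equal(mat$aupr, ref$aupr[ref$level == "nucleotide"])
  # missing combinations are NA, not zero
  mat2 <- cross_tf_matrix(list(A = fit), list(A = ds, B = ds))
  expect_true(all(is.na(mat2$auc[mat2$train_tf == "B"])))
})

test_that("summary-vector correlations are symmetric with unit diagonal", {
  pos <- generate_synthetic(synthetic_spec(6, motif = "CAGCTG", seed = 94))
  ds <- make_dataset(pos, seed = 95)
  fit <- tfsnr_fit(ds, model_config(n_layers = 1L, d_model = 16L, n_heads = 2L),
                   epochs = 0, seed = 96)
  cc <- cls_correlation(fit, ds)
  expect_equal(cc$cor, t(cc$cor))
  expect_equal(unname(diag(cc$cor)), rep(1, 12))
  expect_setequal(cc$order, 1:12)
  # duplicated sequences correlate perfectly
  dup <- ds[c(1, 1, 2), ]
  dup$id <- c("a", "b", "c")
  cc2 <- cls_correlation(fit, dup)
  expect_equal(cc2$cor["a", "b"], 1)
  expect_error(cls_correlation(fit, ds[1, ]), "at least 2")
})

test_that("constant summary vectors are rejected as undefined correlation", {
  pos <- generate_synthetic(synthetic_spec(3, motif = "CAGCTG", seed = 97))
  ds <- make_dataset(pos, seed = 98)
  fit <- tfsnr_fit(ds, model_config(n_layers = 1L, d_model = 16L, n_heads = 2L),
                   epochs = 0, seed = 99)
  # zero every weight: embeddings collapse and LayerNorm emits a constant row
  fit$weights <- lapply(fit$weights, function(w) w * 0)
  expect_error(cls_correlation(fit, ds), "constant")
})

test_that("uniform attention aggregates to a flat non-negative profile", {
  pos <- generate_synthetic(synthetic_spec(4, motif = "CAGCTG", seed = 100))
  fit <- tfsnr_fit(make_dataset(pos, seed = 101),
                   model_config(n_layers = 1L, d_model = 16L, n_heads = 2L),
                   epochs = 0, seed = 102)
  # zeroed query/key projections make every attention row exactly uniform
  fit$weights$l1.attn.Wq <- fit$weights$l1.attn.Wq * 0
  fit$weights$l1.attn.bq <- fit$weights$l1.attn.bq * 0
  fit$weights$l1.attn.Wk <- fit$weights$l1.attn.Wk * 0
  fit$weights$l1.attn.bk <- fit$weights$l1.attn.bk * 0
  prof <- aggregate_attention(fit, pos, layer = 1)
  expect_equal(nrow(prof), 100)
  expect_true(all(prof$mean_weight >= 0))
  expect_lt(diff(range(prof$mean_weight)), 1e-8)
  # ragged sequence lengths are rejected
  ragged <- labeled_sequences(c("r1", "r2"), c("ACGTACGTACGT", "ACGTACGTAC"),
                              list(integer(12), integer(10)))
  expect_error(aggregate_attention(fit, ragged), "same length")
})

test_that("tidy and glance summarize fitted models", {
  pos <- generate_synthetic(synthetic_spec(8, motif = "CAGCTG", seed = 103))
  ds <- make_dataset(pos, seed = 104)
  fit <- tfsnr_fit(ds, model_config(n_layers = 1L, d_model = 16L, n_heads = 2L),
                   epochs = 2, patience = 3, batch_size = 8, seed = 105)
  td <- tidy(fit)
  expect_true(all(c("epoch", "train_loss", "val_loss", "best") %in% names(td)))
  expect_equal(sum(td$best), 1)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_layers, 1L)
  expect_equal(gl$n_params, fit$n_params)
})
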