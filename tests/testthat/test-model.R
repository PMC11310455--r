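test_that("input embeddings are the sum of token and position embeddings", {
  tok_tab <- matrix(rnorm(20), 5, 4)
  pos_tab <- matrix(rnorm(12), 3, 4)
  ids <- c(2L, 0L, 4L)
  expect_equal(embed_tokens(ids, tok_tab, pos_tab),
               tok_tab[ids + 1L, ] + pos_tab[1:3, ])
  expect_equal(embed_tokens(ids, tok_tab, pos_tab * 0), tok_tab[ids + 1L, ])
  expect_equal(embed_tokens(ids, tok_tab * 0, pos_tab * 0),
               matrix(0, 3, 4))
  # one-hot tables: each output row holds two ones (or a single two)
  tok1 <- diag(5)[, 1:4]
  pos1 <- diag(4)[1:3, ]
  out <- embed_tokens(c(0L, 1L, 2L), tok1, pos1)
  expect_true(all(rowSums(out) == 2))
  expect_error(embed_tokens(c(0L, 9L), tok_tab, pos_tab), "out of vocabulary")
})

test_that("a single token attends only to itself", {
  withr::local_seed(51)
  d <- 4
  params <- list(Wq = matrix(rnorm(16), 4, 4), Wk = matrix(rnorm(16), 4, 4),
                 Wv = matrix(rnorm(16), 4, 4), Wo = matrix(rnorm(16), 4, 4),
                 n_heads = 2L)
  X <- matrix(rnorm(d), 1, d)
  res <- multi_head_attention(X, params)
  expect_equal(res$output, X %*% params$Wv %*% params$Wo)
  expect_equal(as.vector(res$attention), rep(1, 2))
})

test_that("zero input gives uniform attention and zero output", {
  params <- list(Wq = diag(3), Wk = diag(3), Wv = diag(3), Wo = diag(3),
                 n_heads = 1L)
  X <- matrix(0, 4, 3)
  res <- multi_head_attention(X, params)
  expect_equal(res$output, matrix(0, 4, 3))
  expect_equal(res$attention[1, , ], matrix(0.25, 4, 4))
})

test_that("attention matches a hand-computed 2-token oracle", {
  # 2 tokens, 1 head, 2-d: every intermediate is computed longhand here,
  # independently of the implementation
  X <- matrix(c(1, 0,
                0, 2), 2, 2, byrow = TRUE)
  Wq <- matrix(c(1, 0, 0, 1), 2, 2)
  Wk <- matrix(c(0, 1, 1, 0), 2, 2)
  Wv <- matrix(c(1, 1, 0, 1), 2, 2)
  Wo <- matrix(c(2, 0, 0, 1), 2, 2)
  Q <- X %*% Wq
  K <- X %*% Wk
  V <- X %*% Wv
  S <- Q %*% t(K) / sqrt(2)
  P <- rbind(exp(S[1, ]) / sum(exp(S[1, ])), exp(S[2, ]) / sum(exp(S[2, ])))
  expected <- (P %*% V) %*% Wo
  res <- multi_head_attention(X, list(Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo,
                                      n_heads = 1L))
  expect_equal(res$output, expected, tolerance = 1e-6)
  expect_equal(res$attention[1, , ], P, tolerance = 1e-6)
})

test_that("attention validates shapes and masks", {
  params <- list(Wq = diag(3), Wk = diag(3), Wv = diag(3), Wo = diag(2),
                 n_heads = 1L)
  expect_error(multi_head_attention(matrix(0, 2, 3), params), "Wo must be")
  params$Wo <- diag(3)
  expect_error(multi_head_attention(matrix(0, 2, 3), params, mask = c(0, 0)),
               "all slots masked")
  res <- multi_head_attention(matrix(rnorm(9), 3, 3), params, mask = c(1, 1, 0))
  expect_equal(res$attention[1, 1:2, 3], c(0, 0))       # masked key column
  expect_equal(rowSums(res$attention[1, 1:2, ]), c(1, 1))
  expect_equal(res$attention[1, 3, ], rep(0, 3))        # masked query row
})

test_that("encoder layer preserves shape and normalizes rows", {
  withr::local_seed(52)
  d <- 6
  params <- list(
    Wq = matrix(rnorm(36, 0, 0.5), d, d), Wk = matrix(rnorm(36, 0, 0.5), d, d),
    Wv = matrix(rnorm(36, 0, 0.5), d, d), Wo = matrix(rnorm(36, 0, 0.5), d, d),
    n_heads = 2L,
    W1 = matrix(rnorm(72, 0, 0.5), d, 12), b1 = rnorm(12),
    W2 = matrix(rnorm(72, 0, 0.5), 12, d), b2 = rnorm(d)
  )
  X <- matrix(rnorm(30), 5, d)
  out <- encoder_layer(X, params)$output
  expect_equal(dim(out), c(5, 6))
  # default gamma=1, beta=0: output rows are standardized
  expect_equal(unname(rowMeans(out)), rep(0, 5), tolerance = 1e-8)
  expect_equal(unname(apply(out, 1, function(r) mean(r^2))), rep(1, 5),
               tolerance = 1e-6)
})

test_that("a zero-sublayer encoder layer reduces to double normalization", {
  d <- 4
  zero <- matrix(0, d, d)
  params <- list(Wq = zero, Wk = zero, Wv = zero, Wo = zero, n_heads = 1L,
                 W1 = matrix(0, d, 8), b1 = rep(0, 8),
                 W2 = matrix(0, 8, d), b2 = rep(0, d))
  X <- matrix(rnorm(20), 5, d)
  # independent longhand LayerNorm
  ln <- function(M) t(apply(M, 1, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-12)
  }))
  expect_equal(encoder_layer(X, params)$output, ln(ln(X)), tolerance = 1e-9)
})

test_that("forward outputs are probabilities and bit-stable across calls", {
  pos <- generate_synthetic(synthetic_spec(4, motif = "CAGCTG", seed = 53))
  ds <- make_dataset(pos, seed = 54)
  fit <- tfsnr_fit(ds, model_config(n_layers = 1L, d_model = 16L, n_heads = 2L),
                   epochs = 0, seed = 55)
  p1 <- predict(fit, ds)
  p2 <- predict(fit, ds)
  expect_identical(p1, p2)
  expect_true(all(p1$seq_prob > 0 & p1$seq_prob < 1))
  expect_true(all(unlist(p1$nuc_probs) > 0 & unlist(p1$nuc_probs) < 1))
  expect_true(all(lengths(p1$nuc_probs) == 100))
})

test_that("an untrained model scores at chance on balanced data", {
  pos <- generate_synthetic(synthetic_spec(250, motif = "CAGCTG", seed = 56))
  ds <- make_dataset(pos, seed = 57)
  fit <- tfsnr_fit(ds, model_config(), epochs = 0, seed = 58)
  pred <- predict(fit, ds)
  auc <- auc_score(pred$seq_prob, pred$seq_label)
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("extra padding never changes predictions on real tokens", {
  pos <- generate_synthetic(synthetic_spec(3, motif = "CAGCTG", seed = 59))
  fit <- tfsnr_fit(make_dataset(pos, seed = 60),
                   model_config(n_layers = 1L, d_model = 16L, n_heads = 2L),
                   epochs = 0, seed = 61)
  v <- fit$vocab
  enc_tight <- tfsnr:::encode_dataset(pos, v, max_len = 101L)
  enc_padded <- tfsnr:::encode_dataset(pos, v, max_len = 120L)
  f1 <- tfsnr:::transformer_forward(fit$weights, fit$config,
                                    enc_tight$input_ids, enc_tight$attention_mask)
  f2 <- tfsnr:::transformer_forward(fit$weights, fit$config,
                                    enc_padded$input_ids, enc_padded$attention_mask)
  expect_equal(f1$seq_logits, f2$seq_logits, tolerance = 1e-10)
  expect_equal(f1$token_logits[, 1:101], f2$token_logits[, 1:101],
               tolerance = 1e-10)
})

test_that("attention rows are stochastic at every layer and head", {
  pos <- generate_synthetic(synthetic_spec(2, motif = "CAGCTG", seed = 62))
  fit <- tfsnr_fit(make_dataset(pos, seed = 63), model_config(),
                   epochs = 0, seed = 64)
  maps <- attention_maps(fit, pos[1, ])
  expect_length(maps, 2)
  for (a in maps) {
    expect_equal(dim(a), c(4, 100, 100))
    for (h in 1:4) {
      expect_equal(unname(rowSums(a[h, , ])), rep(1, 100), tolerance = 1e-5)
    }
  }
})

test_that("multi-task loss obeys its limits and the p = 1/2 closed form", {
  expect_equal(multitask_loss(0.8, 1, c(0.5, 0.5), c(1, 0), 1),
               -log(0.8))
  expect_equal(multitask_loss(0.8, 1, c(0.25, 0.25), c(0, 0), 0),
               -log(0.75))
  expect_equal(multitask_loss(0.5, 1, rep(0.5, 4), rep(1L, 4), 0.5),
               log(2))
  # ignore-marked tokens are excluded from the token mean
  expect_equal(multitask_loss(0.5, 1, c(0.5, 0.9), c(1L, -1L), 0),
               -log(0.5))
  expect_error(multitask_loss(0.5, 1, 0.5, 1L, 1.5), "lambda")
  expect_true(is.finite(multitask_loss(1, 0, c(0, 1), c(1L, 0L), 0.5)))
})

test_that("training loss gradients match finite differences", {
  withr::local_seed(65)
  cfg <- model_config(k = 3, n_layers = 2L, n_heads = 2L, d_model = 8L,
                      d_ff = 16L, max_len = 16L, dropout = 0)
  vocab <- build_vocab(3)
  w <- tfsnr:::init_weights(cfg, length(vocab$tokens))
  # inflate so attention is far from uniform and gradients are O(1e-2)
  w <- lapply(w, function(x) x * 6)
  ds <- labeled_sequences(
    c("a", "b"), c("ACGTACGTNACG", "TTTGGGCCAAAT"),
    list(c(0, 0, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
         c(0, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  )
  enc <- tfsnr:::encode_dataset(ds, vocab, max_len = 16L)
  batch <- list(input_ids = enc$input_ids, token_labels = enc$token_labels,
                attention_mask = enc$attention_mask, seq_label = enc$seq_label)
  lg <- tfsnr:::loss_and_grads(w, cfg, batch)
  lossfn <- function(wts) {
    tfsnr:::loss_and_grads(wts, cfg, batch, want_grads = FALSE)$loss
  }
  eps <- 1e-5
  for (nm in names(w)) {
    len <- length(w[[nm]])
    for (i in sample(len, min(4, len))) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (lossfn(wp) - lossfn(wm)) / (2 * eps)
      ana <- lg$grads[[nm]][i]
      if (abs(num) < 1e-7 && abs(ana) < 1e-7) next
      expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("token probability expansion takes the max over covering k-mers", {
  expect_equal(expand_token_probs(c(0.1, 0.9, 0.1), 3, 5),
               c(0.1, 0.9, 0.9, 0.9, 0.1))
  expect_equal(expand_token_probs(rep(0.42, 5), 2, 6), rep(0.42, 6))
  # binary inputs reproduce the discrete OR expansion
  withr::local_seed(66)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    L <- sample(k:25, 1)
    tok <- as.integer(runif(L - k + 1) < 0.3)
    expect_equal(expand_token_probs(as.numeric(tok), k, L),
                 as.numeric(token_labels_to_nuc_labels(tok, k, L)))
  }
  expect_error(expand_token_probs(c(0.5, 0.5), 3, 6), "expected 4")
})

test_that("expansion commutes with thresholding at any threshold", {
  withr::local_seed(67)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    L <- sample(k:30, 1)
    p <- runif(L - k + 1)
    t <- runif(1, 0.05, 0.95)
    a <- as.integer(expand_token_probs(p, k, L) >= t)
    b <- token_labels_to_nuc_labels(as.integer(p >= t), k, L)
    expect_identical(a, b)
  }
})

test_that("model configuration enforces its invariants", {
  expect_error(model_config(n_heads = 3L, d_model = 64L), "divide")
  expect_error(model_config(lambda_weight = 1.2), "lambda")
  expect_error(model_config(n_layers = 0L), ">= 1")
  cfg <- model_config(n_heads = 8L, d_model = 64L)
  expect_equal(cfg$d_k, 8L)
  full <- model_config_full()
  expect_equal(full$n_layers, 12L)
  expect_equal(full$d_model, 768L)
  expect_equal(full$n_heads * full$d_k, full$d_model)
})
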