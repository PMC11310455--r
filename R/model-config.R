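#' Model configuration
#'
#' Hyperparameters of the k-mer transformer encoder. The full-scale
#' configuration mirrors the BERT-base lineage of DNA language models
#' (12 layers, 768-wide, 12 heads); the default here is a desk-scale encoder
#' (2 layers, 64-wide, 4 heads) that trains in minutes on one CPU while
#' exercising exactly the same code path.
#'
#' @param k k-mer length used for tokenization (default 3).
#' @param n_layers number of encoder layers.
#' @param n_heads number of attention heads; must divide `d_model`.
#' @param d_model embedding / hidden width.
#' @param d_ff feed-forward inner width (default the conventional
#'   `4 * d_model`).
#' @param max_len maximum number of token slots (`[CLS]` + k-mers + `[SEP]`
#'   + padding).
#' @param dropout dropout probability applied to embeddings and residual
#'   branches during training.
#' @param lambda_weight multi-task weight `lambda` in `[0, 1]`: the training
#'   loss is `lambda * BCE(sequence) + (1 - lambda) * BCE(token)`. 0.5 by
#'   default, weighting both tasks equally.
#' @param position_embedding `"sinusoidal"` (fixed tables, default) or
#'   `"learned"` (BERT-style absolute embeddings). Sinusoidal tables encode
#'   relative offsets uniformly across positions, which makes the
#'   adjacent-k-mer composition patterns of motif recognition far more
#'   sample-efficient to learn from scratch; learned absolute embeddings
#'   match the pretrained DNA language-model lineage and suit fine-tuning.
#' @param init_sd standard deviation of the Gaussian weight/embedding
#'   initialization (default 0.1). The classic BERT value, 0.02, suits
#'   fine-tuning from pretrained weights; from-scratch training with so
#'   small an initialization spends hundreds of optimizer steps stuck at
#'   base-rate predictions before features emerge.
#' @param seed integer seed for weight initialization.
#' @return Object of class `tfsnr_config`.
#' @examples
#' model_config()                       # desk-scale default
#' model_config_full()                  # 12-layer full-scale variant
#' @export
model_config <- function(k = 3L, n_layers = 2L, n_heads = 4L, d_model = 64L,
                         d_ff = 4L * d_model, max_len = 128L, dropout = 0.1,
                         lambda_weight = 0.5,
                         position_embedding = c("sinusoidal", "learned"),
                         init_sd = 0.1, seed = 1L) {
  position_embedding <- match.arg(position_embedding)
  cfg <- list(
    k = as.integer(k), n_layers = as.integer(n_layers),
    n_heads = as.integer(n_heads), d_model = as.integer(d_model),
    d_ff = as.integer(d_ff), max_len = as.integer(max_len),
    dropout = dropout, lambda_weight = lambda_weight,
    position_embedding = position_embedding, init_sd = init_sd,
    seed = as.integer(seed)
  )
  if (any(c(cfg$n_layers, cfg$n_heads, cfg$d_model, cfg$d_ff) < 1)) {
    abort("all model dimensions must be >= 1")
  }
  if (cfg$d_model %% cfg$n_heads != 0) {
    abort("n_heads must divide d_model (n_heads * d_k == d_model)")
  }
  cfg$d_k <- cfg$d_model %/% cfg$n_heads
  if (lambda_weight < 0 || lambda_weight > 1) abort("lambda_weight must be in [0, 1]")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(cfg, class = "tfsnr_config")
}

#' @rdname model_config
#' @param ... overrides passed to [model_config()].
#' @export
model_config_full <- function(...) {
  args <- list(...)
  defaults <- list(n_layers = 12L, n_heads = 12L, d_model = 768L,
                   d_ff = 3072L, max_len = 512L,
                   position_embedding = "learned", init_sd = 0.02)
  do.call(model_config, utils::modifyList(defaults, args))
}

#' @export
print.tfsnr_config <- function(x, ...) {
  cat(sprintf(
    "<tfsnr_config> k=%d | %d layers x %d heads, d_model=%d (d_k=%d), d_ff=%d\n",
    x$k, x$n_layers, x$n_heads, x$d_model, x$d_k, x$d_ff))
  cat(sprintf("  max_len=%d, dropout=%g, lambda=%g, positions=%s, seed=%d\n",
              x$max_len, x$dropout, x$lambda_weight, x$position_embedding,
              x$seed))
  invisible(x)
}

# Fixed sinusoidal position table (max_len x d_model).
sinusoidal_table <- function(max_len, d_model) {
  pos <- seq_len(max_len) - 1
  i <- seq_len(d_model) - 1
  angle <- outer(pos, 1 / 10000^((i %/% 2 * 2) / d_model))
  out <- matrix(0, max_len, d_model)
  even <- (i %% 2) == 0
  out[, even] <- sin(angle[, even])
  out[, !even] <- cos(angle[, !even])
  out
}

# Initialize all weights as a flat named list (Gaussian projections and
# embeddings, identity LayerNorm, zero biases).
init_weights <- function(config, vocab_size) {
  sd0 <- config$init_sd %||% 0.02
  d <- config$d_model
  mat <- function(nr, nc) matrix(rnorm(nr * nc, 0, sd0), nr, nc)
  build <- function() {
    w <- list(
      emb.tok = mat(vocab_size, d),
      emb.pos = if (config$position_embedding == "sinusoidal") {
        sinusoidal_table(config$max_len, d)
      } else {
        mat(config$max_len, d)
      },
      emb.ln.g = rep(1, d), emb.ln.b = rep(0, d)
    )
    for (l in seq_len(config$n_layers)) {
      p <- sprintf("l%d.", l)
      w[[paste0(p, "attn.Wq")]] <- mat(d, d)
      w[[paste0(p, "attn.bq")]] <- rep(0, d)
      w[[paste0(p, "attn.Wk")]] <- mat(d, d)
      w[[paste0(p, "attn.bk")]] <- rep(0, d)
      w[[paste0(p, "attn.Wv")]] <- mat(d, d)
      w[[paste0(p, "attn.bv")]] <- rep(0, d)
      w[[paste0(p, "attn.Wo")]] <- mat(d, d)
      w[[paste0(p, "attn.bo")]] <- rep(0, d)
      w[[paste0(p, "ln1.g")]] <- rep(1, d)
      w[[paste0(p, "ln1.b")]] <- rep(0, d)
      w[[paste0(p, "ffn.W1")]] <- mat(d, config$d_ff)
      w[[paste0(p, "ffn.b1")]] <- rep(0, config$d_ff)
      w[[paste0(p, "ffn.W2")]] <- mat(config$d_ff, d)
      w[[paste0(p, "ffn.b2")]] <- rep(0, d)
      w[[paste0(p, "ln2.g")]] <- rep(1, d)
      w[[paste0(p, "ln2.b")]] <- rep(0, d)
    }
    w$head.seq.W <- mat(d, 1)
    w$head.seq.b <- 0
    w$head.tok.W <- mat(d, 1)
    w$head.tok.b <- 0
    w
  }
  withr::with_seed(substream_seed(config$seed, "init"), build())
}

# Number of trainable scalars.
n_parameters <- function(weights) sum(vapply(weights, length, 1L))
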