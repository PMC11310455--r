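# Elementwise helpers exploiting column-major recycling: scale / shift the
# columns of an n x d matrix by a length-d vector.
colscale <- function(X, v) X * rep(v, each = nrow(X))
colshift <- function(X, v) X + rep(v, each = nrow(X))

sigmoid <- function(x) 1 / (1 + exp(-x))

# Exact (erf-based) GELU and its derivative. The derivative reuses the
# forward pass's Phi = pnorm(x) and forms the Gaussian density directly.
gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x, Phi = pnorm(x)) {
  Phi + x * (0.3989422804014327 * exp(-0.5 * x * x))
}

# Row-wise LayerNorm; returns the output plus what the backward pass needs.
LN_EPS <- 1e-12
layer_norm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  list(y = colshift(colscale(xhat, g), b), xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- colscale(dY, g)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dX = dx, dg = colSums(dY * xhat), db = colSums(dY))
}

# Numerically safe row softmax (row max located via C-level max.col).
row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

#' Sum token and position embeddings
#'
#' The composite input embedding of token i is the sum of its token embedding
#' and the embedding of its position: `E_input = E_token + E_position`.
#'
#' @param token_ids integer vector of 0-based token ids.
#' @param token_table vocabulary-size x d embedding matrix.
#' @param position_table max-length x d position embedding matrix.
#' @param positions 0-based positions (defaults to `0, 1, 2, ...`).
#' @return `length(token_ids)` x d matrix.
#' @export
embed_tokens <- function(token_ids, token_table, position_table,
                         positions = seq_along(token_ids) - 1L) {
  if (any(token_ids < 0) || any(token_ids >= nrow(token_table))) {
    abort("token id out of vocabulary range")
  }
  if (any(positions < 0) || any(positions >= nrow(position_table))) {
    abort("position exceeds position-table length")
  }
  token_table[token_ids + 1L, , drop = FALSE] +
    position_table[positions + 1L, , drop = FALSE]
}

#' Multi-head scaled dot-product self-attention (single sequence)
#'
#' Reference implementation of
#' `head_i = softmax(X Wq_i (X Wk_i)^T / sqrt(d_k)) X Wv_i`,
#' `MultiHead(X) = Concat(head_1..head_n) Wo`. Masked slots are excluded from
#' the softmax support and receive zero attention. This single-sequence form
#' backs the exported API and the tests; training uses an equivalent batched
#' path.
#'
#' @param X T x d_model input matrix.
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (d_model x d_model),
#'   optional biases `bq`, `bk`, `bv`, `bo`, and `n_heads`.
#' @param mask optional 0/1 vector of length T; 0 marks padding slots.
#' @return List with `output` (T x d_model) and `attention`
#'   (n_heads x T x T array of row-stochastic maps).
#' @export
multi_head_attention <- function(X, params, mask = NULL) {
  d <- ncol(X)
  Tn <- nrow(X)
  H <- params$n_heads %||% 1L
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    if (!all(dim(params[[nm]]) == c(d, d))) {
      abort(sprintf("parameter %s must be %d x %d", nm, d, d))
    }
  }
  if (d %% H != 0) abort("n_heads must divide d_model")
  dk <- d %/% H
  if (is.null(mask)) mask <- rep(1L, Tn)
  if (all(mask == 0)) abort("attention undefined: all slots masked")
  zero <- rep(0, d)
  Q <- colshift(X %*% params$Wq, params$bq %||% zero)
  K <- colshift(X %*% params$Wk, params$bk %||% zero)
  V <- colshift(X %*% params$Wv, params$bv %||% zero)
  Ctx <- matrix(0, Tn, d)
  att <- array(0, c(H, Tn, Tn))
  for (h in seq_len(H)) {
    ch <- ((h - 1) * dk + 1):(h * dk)
    S <- Q[, ch, drop = FALSE] %*% t(K[, ch, drop = FALSE]) / sqrt(dk)
    S[, mask == 0] <- -Inf
    P <- row_softmax(S)
    P[mask == 0, ] <- 0  # padding queries carry no attention mass
    att[h, , ] <- P
    Ctx[, ch] <- P %*% V[, ch, drop = FALSE]
  }
  out <- colshift(Ctx %*% params$Wo, params$bo %||% zero)
  list(output = out, attention = att)
}

#' One transformer encoder layer (single sequence)
#'
#' Two residual sub-layers in post-norm arrangement,
#' `LayerNorm(x + Sublayer(x))`: multi-head self-attention followed by a
#' position-wise feed-forward network (GELU nonlinearity).
#'
#' @param X T x d_model input.
#' @param params list with the attention parameters of
#'   [multi_head_attention()] plus `ln1_g`, `ln1_b`, `W1`, `b1`, `W2`, `b2`,
#'   `ln2_g`, `ln2_b`.
#' @param mask optional 0/1 slot mask.
#' @return List with `output` (T x d_model) and `attention`.
#' @export
encoder_layer <- function(X, params, mask = NULL) {
  d <- ncol(X)
  mha <- multi_head_attention(X, params, mask)
  ln1 <- layer_norm_fwd(X + mha$output, params$ln1_g %||% rep(1, d),
                        params$ln1_b %||% rep(0, d))
  H1 <- ln1$y
  FF <- colshift(gelu(colshift(H1 %*% params$W1, params$b1)) %*% params$W2,
                 params$b2)
  ln2 <- layer_norm_fwd(H1 + FF, params$ln2_g %||% rep(1, d),
                        params$ln2_b %||% rep(0, d))
  list(output = ln2$y, attention = mha$attention)
}

# ---------------------------------------------------------------------------
# Batched forward pass used for training and prediction.
#
# ids, mask: B x T matrices (0-based ids). Activations are stacked as a
# (B*T) x d matrix with rows grouped by sequence. Returns logits, the final
# hidden states, optionally per-layer attention arrays (B x H x T x T), and
# the cache consumed by transformer_backward().
transformer_forward <- function(weights, config, ids, mask,
                                dropout_active = FALSE,
                                collect_attention = FALSE,
                                keep_cache = FALSE) {
  B <- nrow(ids)
  Tn <- ncol(ids)
  d <- config$d_model
  H <- config$n_heads
  dk <- config$d_k
  p_drop <- if (dropout_active) config$dropout else 0
  drop_mask <- function(n, m) {
    if (p_drop > 0) {
      matrix((runif(n * m) >= p_drop) / (1 - p_drop), n, m)
    } else NULL
  }
  apply_drop <- function(X, dm) if (is.null(dm)) X else X * dm

  if (Tn > config$max_len) abort("input longer than config max_len")
  idvec <- as.vector(t(ids)) + 1L
  if (any(idvec < 1L) || any(idvec > nrow(weights$emb.tok))) {
    abort("token id out of vocabulary range")
  }
  posvec <- rep(seq_len(Tn), B)
  X0raw <- weights$emb.tok[idvec, , drop = FALSE] +
    weights$emb.pos[posvec, , drop = FALSE]
  ln_emb <- layer_norm_fwd(X0raw, weights$emb.ln.g, weights$emb.ln.b)
  dm_emb <- drop_mask(B * Tn, d)
  X <- apply_drop(ln_emb$y, dm_emb)

  cache <- if (keep_cache) {
    list(ids = ids, mask = mask, idvec = idvec, posvec = posvec,
         ln_emb = ln_emb, dm_emb = dm_emb, B = B, Tn = Tn, layers = vector("list", config$n_layers))
  } else NULL
  attn_out <- if (collect_attention) vector("list", config$n_layers) else NULL

  neg <- -1e9
  row_idx <- function(b) ((b - 1) * Tn + 1):(b * Tn)

  for (l in seq_len(config$n_layers)) {
    p <- sprintf("l%d.", l)
    X_in <- X
    Q <- colshift(X %*% weights[[paste0(p, "attn.Wq")]], weights[[paste0(p, "attn.bq")]])
    K <- colshift(X %*% weights[[paste0(p, "attn.Wk")]], weights[[paste0(p, "attn.bk")]])
    V <- colshift(X %*% weights[[paste0(p, "attn.Wv")]], weights[[paste0(p, "attn.bv")]])
    Ctx <- matrix(0, B * Tn, d)
    P_all <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- row_idx(b)
      mb <- mask[b, ]
      P_all[[b]] <- vector("list", H)
      for (h in seq_len(H)) {
        ch <- ((h - 1) * dk + 1):(h * dk)
        S <- tcrossprod(Q[rb, ch, drop = FALSE], K[rb, ch, drop = FALSE]) / sqrt(dk)
        if (any(mb == 0)) S[, mb == 0] <- neg
        P <- row_softmax(S)
        P_all[[b]][[h]] <- P
        Ctx[rb, ch] <- P %*% V[rb, ch, drop = FALSE]
      }
    }
    A <- colshift(Ctx %*% weights[[paste0(p, "attn.Wo")]], weights[[paste0(p, "attn.bo")]])
    dm1 <- drop_mask(B * Tn, d)
    R1 <- X_in + apply_drop(A, dm1)
    ln1 <- layer_norm_fwd(R1, weights[[paste0(p, "ln1.g")]], weights[[paste0(p, "ln1.b")]])
    H1 <- ln1$y
    Z1 <- colshift(H1 %*% weights[[paste0(p, "ffn.W1")]], weights[[paste0(p, "ffn.b1")]])
    Phi <- pnorm(Z1)
    G <- Z1 * Phi
    FF <- colshift(G %*% weights[[paste0(p, "ffn.W2")]], weights[[paste0(p, "ffn.b2")]])
    dm2 <- drop_mask(B * Tn, d)
    R2 <- H1 + apply_drop(FF, dm2)
    ln2 <- layer_norm_fwd(R2, weights[[paste0(p, "ln2.g")]], weights[[paste0(p, "ln2.b")]])
    X <- ln2$y

    if (collect_attention) {
      # pack into a B x H x T x T array, zeroing padding-query rows so stored
      # maps are 0 on masked slots
      Pz <- array(0, c(B, H, Tn, Tn))
      for (b in seq_len(B)) {
        mb <- mask[b, ]
        for (h in seq_len(H)) {
          P <- P_all[[b]][[h]]
          if (any(mb == 0)) P[mb == 0, ] <- 0
          Pz[b, h, , ] <- P
        }
      }
      attn_out[[l]] <- Pz
    }
    if (keep_cache) {
      cache$layers[[l]] <- list(X_in = X_in, Q = Q, K = K, V = V, P = P_all,
                                Ctx = Ctx, dm1 = dm1, ln1 = ln1, H1 = H1,
                                Z1 = Z1, Phi = Phi, G = G, dm2 = dm2, ln2 = ln2)
    }
  }

  cls_rows <- ((seq_len(B) - 1) * Tn) + 1L
  seq_logits <- as.vector(X[cls_rows, , drop = FALSE] %*% weights$head.seq.W) +
    weights$head.seq.b
  token_logits <- matrix(as.vector(X %*% weights$head.tok.W) + weights$head.tok.b,
                         B, Tn, byrow = TRUE)
  if (keep_cache) cache$H_final <- X
  list(seq_logits = seq_logits, token_logits = token_logits,
       hidden = X, cls = X[cls_rows, , drop = FALSE],
       attention = attn_out, cache = cache)
}

#' Expand k-mer token probabilities to nucleotide probabilities
#'
#' Nucleotide j receives the maximum probability among all tokens whose k-mer
#' covers j — the continuous analogue of the OR expansion used for binary
#' labels. Using the max (rather than, say, the mean) makes expansion commute
#' with thresholding: expanding then thresholding at any t equals
#' OR-expanding the thresholded token labels.
#'
#' @param token_probs numeric vector of length `L - k + 1`.
#' @param k k-mer length.
#' @param L nucleotide sequence length.
#' @return Numeric vector of length L.
#' @examples
#' expand_token_probs(c(0.1, 0.9, 0.1), 3, 5)  # 0.1 0.9 0.9 0.9 0.1
#' @export
expand_token_probs <- function(token_probs, k, L) {
  n_tok <- length(token_probs)
  if (n_tok != L - k + 1) {
    abort(sprintf("expected %d token probabilities for L = %d, k = %d; got %d",
                  L - k + 1, L, k, n_tok))
  }
  vapply(seq_len(L), function(j) {
    max(token_probs[max(1L, j - k + 1L):min(j, n_tok)])
  }, 0)
}

#' Multi-task training loss
#'
#' `lambda * BCE(seq_prob, seq_label) + (1 - lambda) * mean BCE over
#' included tokens`, both terms binary cross-entropies. Token labels equal
#' to -1 (special and padding slots) are excluded from the token mean.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` so the loss stays finite.
#'
#' @param seq_prob sequence-level probability in (0, 1).
#' @param seq_label 0/1 sequence label.
#' @param token_probs per-token probabilities.
#' @param token_labels per-token labels (0/1, or -1 to ignore).
#' @param lambda multi-task weight in `[0, 1]`.
#' @return Scalar loss.
#' @examples
#' multitask_loss(0.5, 1, rep(0.5, 4), rep(1, 4), 0.5)  # log(2)
#' @export
multitask_loss <- function(seq_prob, seq_label, token_probs, token_labels,
                           lambda = 0.5) {
  if (lambda < 0 || lambda > 1) abort("lambda must be in [0, 1]")
  eps <- 1e-7
  bce <- function(p, y) {
    p <- pmin(pmax(p, eps), 1 - eps)
    -(y * log(p) + (1 - y) * log(1 - p))
  }
  incl <- token_labels >= 0
  tok_term <- if (any(incl)) {
    mean(bce(token_probs[incl], token_labels[incl]))
  } else 0
  lambda * bce(seq_prob, seq_label) + (1 - lambda) * tok_term
}
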