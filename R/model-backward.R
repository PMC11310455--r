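# Analytic backward pass mirroring transformer_forward(). Given gradients of
# the loss w.r.t. the sequence and token logits, returns gradients for every
# weight array (same names/shapes as the weight list). Verified against
# finite differences in the test suite.
transformer_backward <- function(weights, config, cache,
                                 dseq_logits, dtoken_logits) {
  B <- cache$B
  Tn <- cache$Tn
  d <- config$d_model
  H <- config$n_heads
  dk <- config$d_k
  mask <- cache$mask
  grads <- list()

  # head layers
  Hf <- cache$H_final
  cls_rows <- ((seq_len(B) - 1) * Tn) + 1L
  dtok_vec <- as.vector(t(dtoken_logits))               # row order matches Hf
  dX <- dtok_vec %*% t(weights$head.tok.W)              # (B*Tn) x d via outer
  dX <- matrix(dX, B * Tn, d)
  grads$head.tok.W <- crossprod(Hf, dtok_vec)
  grads$head.tok.b <- sum(dtok_vec)
  grads$head.seq.W <- crossprod(Hf[cls_rows, , drop = FALSE], dseq_logits)
  grads$head.seq.b <- sum(dseq_logits)
  dX[cls_rows, ] <- dX[cls_rows, ] +
    dseq_logits %*% t(weights$head.seq.W)

  row_idx <- function(b) ((b - 1) * Tn + 1):(b * Tn)
  apply_drop <- function(X, dm) if (is.null(dm)) X else X * dm

  for (l in rev(seq_len(config$n_layers))) {
    p <- sprintf("l%d.", l)
    cl <- cache$layers[[l]]

    lb2 <- layer_norm_bwd(dX, cl$ln2, weights[[paste0(p, "ln2.g")]])
    grads[[paste0(p, "ln2.g")]] <- lb2$dg
    grads[[paste0(p, "ln2.b")]] <- lb2$db
    dR2 <- lb2$dX
    dFF <- apply_drop(dR2, cl$dm2)
    dG <- dFF %*% t(weights[[paste0(p, "ffn.W2")]])
    grads[[paste0(p, "ffn.W2")]] <- crossprod(cl$G, dFF)
    grads[[paste0(p, "ffn.b2")]] <- colSums(dFF)
    dZ1 <- dG * gelu_grad(cl$Z1, cl$Phi)
    grads[[paste0(p, "ffn.W1")]] <- crossprod(cl$H1, dZ1)
    grads[[paste0(p, "ffn.b1")]] <- colSums(dZ1)
    dH1 <- dZ1 %*% t(weights[[paste0(p, "ffn.W1")]]) + dR2

    lb1 <- layer_norm_bwd(dH1, cl$ln1, weights[[paste0(p, "ln1.g")]])
    grads[[paste0(p, "ln1.g")]] <- lb1$dg
    grads[[paste0(p, "ln1.b")]] <- lb1$db
    dR1 <- lb1$dX
    dA <- apply_drop(dR1, cl$dm1)

    # attention output projection
    dCtx <- dA %*% t(weights[[paste0(p, "attn.Wo")]])
    grads[[paste0(p, "attn.Wo")]] <- crossprod(cl$Ctx, dA)
    grads[[paste0(p, "attn.bo")]] <- colSums(dA)

    dQ <- matrix(0, B * Tn, d)
    dK <- matrix(0, B * Tn, d)
    dV <- matrix(0, B * Tn, d)
    for (b in seq_len(B)) {
      rb <- row_idx(b)
      for (h in seq_len(H)) {
        ch <- ((h - 1) * dk + 1):(h * dk)
        P <- cl$P[[b]][[h]]
        dCtxbh <- dCtx[rb, ch, drop = FALSE]
        dP <- tcrossprod(dCtxbh, cl$V[rb, ch, drop = FALSE])
        dV[rb, ch] <- dV[rb, ch] + crossprod(P, dCtxbh)
        dS <- P * (dP - rowSums(dP * P))      # softmax backward, row-wise
        dS <- dS / sqrt(dk)
        dQ[rb, ch] <- dQ[rb, ch] + dS %*% cl$K[rb, ch, drop = FALSE]
        dK[rb, ch] <- dK[rb, ch] + crossprod(dS, cl$Q[rb, ch, drop = FALSE])
      }
    }
    Xin <- cl$X_in
    grads[[paste0(p, "attn.Wq")]] <- crossprod(Xin, dQ)
    grads[[paste0(p, "attn.bq")]] <- colSums(dQ)
    grads[[paste0(p, "attn.Wk")]] <- crossprod(Xin, dK)
    grads[[paste0(p, "attn.bk")]] <- colSums(dK)
    grads[[paste0(p, "attn.Wv")]] <- crossprod(Xin, dV)
    grads[[paste0(p, "attn.bv")]] <- colSums(dV)
    dX <- dR1 +
      dQ %*% t(weights[[paste0(p, "attn.Wq")]]) +
      dK %*% t(weights[[paste0(p, "attn.Wk")]]) +
      dV %*% t(weights[[paste0(p, "attn.Wv")]])
  }

  # embeddings
  dXln <- apply_drop(dX, cache$dm_emb)
  lbe <- layer_norm_bwd(dXln, cache$ln_emb, weights$emb.ln.g)
  grads$emb.ln.g <- lbe$dg
  grads$emb.ln.b <- lbe$db
  dX0 <- lbe$dX
  dTok <- matrix(0, nrow(weights$emb.tok), d)
  agg <- rowsum(dX0, group = cache$idvec)
  dTok[as.integer(rownames(agg)), ] <- agg
  grads$emb.tok <- dTok
  dPos <- matrix(0, nrow(weights$emb.pos), d)
  aggp <- rowsum(dX0, group = cache$posvec)
  dPos[as.integer(rownames(aggp)), ] <- aggp
  grads$emb.pos <- dPos
  grads
}

# Forward + loss + backward for one encoded batch. `batch` is a subset of an
# encode_dataset() result. The loss is the multi-task objective:
# lambda * mean-over-sequences BCE(seq) +
# (1-lambda) * mean-over-sequences (mean BCE over that sequence's tokens).
loss_and_grads <- function(weights, config, batch, dropout_active = FALSE,
                           want_grads = TRUE) {
  ids <- batch$input_ids
  mask <- batch$attention_mask
  tok_labs <- batch$token_labels
  y <- batch$seq_label
  B <- nrow(ids)
  lambda <- config$lambda_weight

  fw <- transformer_forward(weights, config, ids, mask,
                            dropout_active = dropout_active,
                            keep_cache = want_grads)
  p_seq <- sigmoid(fw$seq_logits)
  p_tok <- sigmoid(fw$token_logits)

  eps <- 1e-7
  clamp <- function(p) pmin(pmax(p, eps), 1 - eps)
  bce <- function(p, y) -(y * log(clamp(p)) + (1 - y) * log(1 - clamp(p)))

  incl <- tok_labs >= 0
  n_incl <- rowSums(incl)
  tok_loss_mat <- bce(p_tok, pmax(tok_labs, 0)) * incl
  tok_loss_per_seq <- rowSums(tok_loss_mat) / pmax(n_incl, 1)
  loss <- lambda * mean(bce(p_seq, y)) + (1 - lambda) * mean(tok_loss_per_seq)

  if (!is.finite(loss)) abort("non-finite training loss")
  if (!want_grads) return(list(loss = loss, p_seq = p_seq, p_tok = p_tok))

  dseq <- lambda * (p_seq - y) / B
  dtok <- (1 - lambda) * (p_tok - pmax(tok_labs, 0)) * incl /
    (pmax(n_incl, 1) * B)
  grads <- transformer_backward(weights, config, fw$cache, dseq, dtok)
  list(loss = loss, grads = grads, p_seq = p_seq, p_tok = p_tok)
}
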