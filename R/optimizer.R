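# Adam with linear learning-rate warmup, the fine-tuning default of the
# BERT/DNA-language-model lineage. State holds first/second moment estimates
# per weight array.
adam_init <- function(weights) {
  list(
    m = lapply(weights, function(w) w * 0),
    v = lapply(weights, function(w) w * 0),
    t = 0L
  )
}

# Global-norm gradient clipping (BERT-lineage default cap 1.0).
clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

# Decoupled weight decay (AdamW) is applied to weight matrices but not to
# biases, LayerNorm parameters, or one-dimensional arrays, per convention.
adam_step <- function(state, weights, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, warmup_steps = 0L,
                      weight_decay = 0, skip = character(0)) {
  state$t <- state$t + 1L
  t <- state$t
  lr_t <- if (warmup_steps > 0 && t < warmup_steps) lr * t / warmup_steps else lr
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(weights)) {
    if (nm %in% skip) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    step <- lr_t * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && is.matrix(weights[[nm]])) {
      step <- step + lr_t * weight_decay * weights[[nm]]
    }
    weights[[nm]] <- weights[[nm]] - step
  }
  list(state = state, weights = weights)
}
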