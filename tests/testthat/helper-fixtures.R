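# Shared fixtures and independent oracles, all built in code at test time.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# 16-bin dinucleotide count vector (independent of the shuffle code path)
dinuc_counts <- function(x) {
  ch <- strsplit(x, "")[[1]]
  lv <- paste0(rep(c("A", "C", "G", "T"), each = 4), c("A", "C", "G", "T"))
  table(factor(paste0(head(ch, -1), tail(ch, -1)), levels = lv))
}

# brute-force oracles for the nucleotide <-> token label maps
oracle_token_labels <- function(nuc, k) {
  L <- length(nuc)
  vapply(seq_len(L - k + 1), function(i) as.integer(all(nuc[i:(i + k - 1)] == 1)), 0L)
}
oracle_nuc_labels <- function(tok, k, L) {
  out <- integer(L)
  for (i in seq_along(tok)) if (tok[i] == 1) out[i:(i + k - 1)] <- 1L
  out
}
erase_short_runs <- function(v, k) {
  r <- rle(v)
  r$values[r$values == 1 & r$lengths < k] <- 0L
  inverse.rle(r)
}

# brute-force average-precision oracle (explicit threshold sweep)
oracle_aupr <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  ap <- 0
  prev_tp <- 0
  for (t in ths) {
    call <- scores >= t
    tp <- sum(call & labels == 1)
    prec <- tp / sum(call)
    ap <- ap + (tp - prev_tp) * prec
    prev_tp <- tp
  }
  ap / n1
}

# dataset with the planted site pinned to the window center
centered_dataset <- function(n, motif = "CAGCTG", window = 100L, seed = 99L) {
  withr::with_seed(seed, {
    w <- nchar(motif)
    off <- (window - w) %/% 2L
    rows <- lapply(seq_len(n), function(i) {
      seqs <- paste0(random_dna(off), motif, random_dna(window - off - w))
      labs <- integer(window)
      labs[(off + 1):(off + w)] <- 1L
      labeled_sequences(sprintf("c%03d", i), seqs, list(labs))
    })
    dplyr::bind_rows(rows)
  })
}

# --- memoized trained models -----------------------------------------------
# Trained once per test run and shared across test files, so the suite pays
# each training cost a single time.
.model_cache <- new.env(parent = emptyenv())

# the full planted-motif recovery experiment: 2000 positive/negative pairs,
# 80/20 split, desk-scale encoder, at most 10 epochs with early stopping
recovery_experiment <- function() {
  if (is.null(.model_cache$recovery)) {
    pos <- generate_synthetic(synthetic_spec(2000, motif = "CAGCTG", seed = 11))
    ds <- make_dataset(pos, seed = 12)
    sp <- split_dataset(ds, 0.8, seed = 13)
    fit <- tfsnr_fit(sp$train, model_config(), epochs = 10, seed = 14)
    .model_cache$recovery <- list(
      fit = fit, train = sp$train, test = sp$test,
      truth_pwm = attr(pos, "truth_pwm")
    )
  }
  .model_cache$recovery
}

# companion factors for the cross-factor transfer experiment (smaller
# training sets: the transfer comparisons are row-wise, each model against
# its own home test set, so companion strength need not match)
transfer_models <- function() {
  if (is.null(.model_cache$transfer)) {
    make_tf <- function(motif, seed) {
      pos <- generate_synthetic(synthetic_spec(600, motif = motif, seed = seed))
      ds <- make_dataset(pos, seed = seed + 1)
      sp <- split_dataset(ds, 0.8, seed = seed + 2)
      fit <- tfsnr_fit(sp$train, model_config(), epochs = 10, seed = seed + 3)
      list(fit = fit, test = sp$test)
    }
    .model_cache$transfer <- list(
      same = make_tf("CAGCTG", 401),   # shares the recovery motif
      diff = make_tf("TTTAAA", 501)    # disjoint motif
    )
  }
  .model_cache$transfer
}
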