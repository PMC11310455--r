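#' The five special tokens
#'
#' `[CLS]` (sequence-summary head token), `[PAD]` (padding), `[UNK]`
#' (k-mers containing non-ACGT characters), `[SEP]` (end-of-sequence) and
#' `[MASK]` (reserved for masked-token objectives), in their canonical id
#' order.
#'
#' @return Character vector of length 5.
#' @export
special_tokens <- function() c("[CLS]", "[PAD]", "[UNK]", "[SEP]", "[MASK]")

#' Build the k-mer vocabulary
#'
#' The vocabulary holds every length-k string over `A,C,G,T` plus the five
#' special tokens, `4^k + 5` entries in all (69 for k = 3). Ordering is fixed
#' — specials first, then k-mers lexicographically — so vocabularies (and
#' hence checkpoints) are portable across sessions. Ids are 0-based.
#'
#' @param k k-mer length. The conventional range is 3-6; values outside it
#'   are allowed with a warning.
#' @return Object of class `kmer_vocab` with elements `k`, `tokens`
#'   (character vector, id = position - 1) and `ids` (named integer lookup).
#' @examples
#' v <- build_vocab(3)
#' length(v$tokens)  # 69
#' @export
build_vocab <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) abort("k must be a positive integer")
  if (k < 3 || k > 6) warn(sprintf("k = %d is outside the conventional 3-6 range", k))
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                           stringsAsFactors = FALSE)))
  kmers <- sort(kmers)
  tokens <- c(special_tokens(), kmers)
  structure(
    list(k = k, tokens = tokens,
         ids = setNames(seq_along(tokens) - 1L, tokens)),
    class = "kmer_vocab"
  )
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab> k = %d, %d tokens (4^k + 5)\n", x$k, length(x$tokens)))
  invisible(x)
}

#' Tokenize a DNA sequence into overlapping k-mers
#'
#' A sequence of length L yields its L - k + 1 overlapping k-mers in order,
#' e.g. `"ATCGAT"` with k = 3 gives `ATC, TCG, CGA, GAT`. k-mers containing
#' any non-ACGT character (such as `N`) are replaced by the `[UNK]` token
#' string.
#'
#' @param seq DNA string, length >= k.
#' @param k k-mer length.
#' @return Character vector of k-mer tokens.
#' @examples
#' tokenize("ATCGAT", 3)
#' @export
tokenize <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) abort("sequence shorter than k")
  starts <- seq_len(L - k + 1)
  kmers <- substring(seq, starts, starts + k - 1)
  kmers[grepl("[^ACGT]", kmers)] <- "[UNK]"
  kmers
}

#' Map nucleotide labels to k-mer token labels
#'
#' A token covering nucleotides i..i+k-1 is labeled 1 only when all k covered
#' nucleotides are labeled 1 (AND rule); partial overlap with a binding site
#' yields 0. A consequence is that 1-runs shorter than k produce no positive
#' tokens.
#'
#' @param nuc_labels integer 0/1 vector, length >= k.
#' @param k k-mer length.
#' @return Integer 0/1 vector of length `length(nuc_labels) - k + 1`.
#' @examples
#' nuc_labels_to_token_labels(c(0, 0, 1, 1, 1, 0), 3)  # 0 0 1 0
#' @export
nuc_labels_to_token_labels <- function(nuc_labels, k) {
  if (any(!nuc_labels %in% c(0, 1))) abort("nuc_labels must be 0/1")
  L <- length(nuc_labels)
  if (L < k) abort("label vector shorter than k")
  cs <- c(0, cumsum(nuc_labels))
  win <- cs[(k + 1):(L + 1)] - cs[1:(L - k + 1)]
  as.integer(win == k)
}

#' Map k-mer token labels back to nucleotide labels
#'
#' A nucleotide is labeled 1 when any token whose k-mer covers it is labeled
#' 1 (OR expansion) — the inverse direction of
#' [nuc_labels_to_token_labels()]. The two maps are mutual inverses exactly
#' on label vectors whose 1-runs all have length >= k; shorter runs are
#' erased by the AND rule and cannot be recovered.
#'
#' @param token_labels integer 0/1 vector of length `L - k + 1`.
#' @param k k-mer length.
#' @param L nucleotide sequence length.
#' @return Integer 0/1 vector of length L.
#' @examples
#' token_labels_to_nuc_labels(c(0, 0, 1, 0), 3, 6)  # 0 0 1 1 1 0
#' @export
token_labels_to_nuc_labels <- function(token_labels, k, L) {
  if (any(!token_labels %in% c(0, 1))) abort("token_labels must be 0/1")
  if (length(token_labels) != L - k + 1) {
    abort(sprintf("expected %d token labels for L = %d, k = %d; got %d",
                  L - k + 1, L, k, length(token_labels)))
  }
  n_tok <- length(token_labels)
  cs <- c(0, cumsum(token_labels))
  j <- seq_len(L)
  lo <- pmax(1L, j - k + 1L)
  hi <- pmin(j, n_tok)
  as.integer(cs[hi + 1] - cs[lo] > 0)
}

#' Encode a labeled sequence for the model
#'
#' Assembles the model input: `[CLS]`, the k-mer token ids, `[SEP]`, then
#' `[PAD]` up to `max_len`. Token labels follow the AND rule of
#' [nuc_labels_to_token_labels()]; special and pad slots carry the ignore
#' marker -1 and are excluded from the token-level loss. `[UNK]` tokens keep
#' their real 0/1 label and stay in the loss. The attention mask is 1 on
#' `[CLS]`, k-mers and `[SEP]`, 0 on padding.
#'
#' @param labeled_seq one row of a labeled dataset (or a list with `seq` and
#'   `nuc_labels`).
#' @param vocab vocabulary from [build_vocab()].
#' @param max_len total slot count after padding.
#' @return Object of class `tokenized_example`: list with `input_ids`
#'   (0-based), `token_labels` (-1 = ignore), `attention_mask`, `n_kmers`,
#'   `k`, `L`, `id`.
#' @export
encode_example <- function(labeled_seq, vocab, max_len = 128L) {
  seq <- labeled_seq$seq[[1]]
  labs <- labeled_seq$nuc_labels[[1]]
  k <- vocab$k
  kmers <- tokenize(seq, k)
  n_kmers <- length(kmers)
  need <- n_kmers + 2L
  if (need > max_len) {
    abort(sprintf("sequence needs %d slots but max_len is %d; increase max_len",
                  need, max_len))
  }
  ids <- unname(vocab$ids[c("[CLS]", kmers, "[SEP]",
                            rep("[PAD]", max_len - need))])
  tok_labs <- c(-1L, nuc_labels_to_token_labels(labs, k), -1L,
                rep(-1L, max_len - need))
  mask <- c(rep(1L, need), rep(0L, max_len - need))
  structure(
    list(input_ids = ids, token_labels = tok_labs, attention_mask = mask,
         n_kmers = n_kmers, k = k, L = nchar(seq),
         id = if (!is.null(labeled_seq$id)) labeled_seq$id[[1]] else NA_character_),
    class = "tokenized_example"
  )
}

# Encode a whole dataset into id/label/mask matrices (one row per sequence).
# max_len defaults to the tightest length that fits every sequence.
encode_dataset <- function(dataset, vocab, max_len = NULL) {
  validate_dataset(dataset)
  lens <- nchar(dataset$seq)
  need <- max(lens) - vocab$k + 3L
  if (is.null(max_len)) max_len <- need
  if (max_len < need) abort("max_len too small for the longest sequence")
  n <- nrow(dataset)
  ids <- matrix(vocab$ids[["[PAD]"]], n, max_len)
  labs <- matrix(-1L, n, max_len)
  mask <- matrix(0L, n, max_len)
  for (i in seq_len(n)) {
    ex <- encode_example(dataset[i, ], vocab, max_len)
    ids[i, ] <- ex$input_ids
    labs[i, ] <- ex$token_labels
    mask[i, ] <- ex$attention_mask
  }
  list(input_ids = ids, token_labels = labs, attention_mask = mask,
       seq_label = dataset$seq_label, id = dataset$id,
       L = lens, k = vocab$k, max_len = max_len)
}
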