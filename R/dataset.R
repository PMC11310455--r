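#' Labeled sequence datasets
#'
#' A labeled dataset is an ordinary tibble with one row per sequence and the
#' columns:
#' \describe{
#'   \item{id}{unique sequence identifier (character)}
#'   \item{seq}{DNA string over `A,C,G,T,N`}
#'   \item{nuc_labels}{list-column of integer 0/1 vectors, one label per
#'     nucleotide; 1 marks positions inside a binding site}
#'   \item{seq_label}{integer 0/1; 1 iff any nucleotide label is 1}
#'   \item{pair_id}{(optional) identifier tying a positive to its shuffled
#'     negative twin, used for leakage-free splitting}
#' }
#'
#' @param id character vector of unique ids.
#' @param seq character vector of DNA strings.
#' @param nuc_labels list of integer 0/1 vectors, one per sequence, each the
#'   same length as its sequence.
#' @param seq_label optional integer 0/1 vector; derived from `nuc_labels`
#'   when omitted.
#' @return A tibble with the columns described above.
#' @examples
#' labeled_sequences("s1", "ACGTAC", list(c(0L, 1L, 1L, 1L, 0L, 0L)))
#' @export
labeled_sequences <- function(id, seq, nuc_labels, seq_label = NULL) {
  seq <- toupper(seq)
  if (is.null(seq_label)) {
    seq_label <- vapply(nuc_labels, function(x) as.integer(any(x == 1L)), 1L)
  }
  out <- tibble(
    id = as.character(id), seq = seq,
    nuc_labels = lapply(nuc_labels, as.integer),
    seq_label = as.integer(seq_label)
  )
  validate_dataset(out)
  out
}

# Internal invariant checks shared by constructors and readers.
validate_dataset <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("id", "seq", "nuc_labels", "seq_label")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("dataset is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(data$id)) abort("duplicate sequence ids in dataset")
  len_ok <- mapply(function(s, l) nchar(s) == length(l), data$seq, data$nuc_labels)
  if (!all(len_ok)) {
    abort(paste0("label/sequence length mismatch for record(s): ",
                 paste(head(data$id[!len_ok], 5), collapse = ", ")))
  }
  bad_lab <- vapply(data$nuc_labels, function(x) any(!x %in% c(0L, 1L)), TRUE)
  if (any(bad_lab)) abort("nuc_labels must be 0/1")
  derived <- vapply(data$nuc_labels, function(x) as.integer(any(x == 1L)), 1L)
  if (!all(derived == data$seq_label)) {
    abort("seq_label must be 1 iff any nucleotide label is 1")
  }
  invisible(data)
}

#' Place a binding site inside a fixed-length window
#'
#' Builds one positive training sequence by embedding a binding-site sequence
#' at a uniformly random offset within a window of `window_len` bp, padding
#' with genomic flanking context. Nucleotide labels are 1 exactly on the site
#' span. Coordinates are 0-based half-open throughout the package; convert
#' 1-based inclusive interval inputs by subtracting 1 from the start.
#'
#' @param site_seq DNA string of the binding site.
#' @param left_flank,right_flank DNA context immediately left/right of the
#'   site. Each side should be at least `window_len - nchar(site_seq)` long so
#'   that every offset in `[0, window_len - site_len]` is realizable.
#' @param window_len window size in bp (default 100).
#' @param id id for the returned record.
#' @return One-row labeled dataset (see [labeled_sequences()]) with extra
#'   columns `site_start`/`site_end` (0-based half-open site span in the
#'   window).
#' @examples
#' withr::with_seed(1, {
#'   extract_window("CAGCTG", strrep("A", 100), strrep("T", 100), 100)
#' })
#' @export
extract_window <- function(site_seq, left_flank, right_flank,
                           window_len = 100L, id = "window_1") {
  site_seq <- toupper(site_seq)
  site_len <- nchar(site_seq)
  if (site_len > window_len) abort("site exceeds window")
  slack <- window_len - site_len
  offset <- if (slack == 0L) 0L else sample.int(slack + 1L, 1L) - 1L
  need_left <- offset
  need_right <- slack - offset
  if (nchar(left_flank) < need_left) {
    abort(sprintf("left flank too short: need %d bp, have %d",
                  need_left, nchar(left_flank)))
  }
  if (nchar(right_flank) < need_right) {
    abort(sprintf("right flank too short: need %d bp, have %d",
                  need_right, nchar(right_flank)))
  }
  left <- if (need_left > 0) substr(toupper(left_flank),
                                    nchar(left_flank) - need_left + 1L,
                                    nchar(left_flank)) else ""
  right <- if (need_right > 0) substr(toupper(right_flank), 1L, need_right) else ""
  seq <- paste0(left, site_seq, right)
  labels <- integer(window_len)
  labels[(offset + 1L):(offset + site_len)] <- 1L
  out <- labeled_sequences(id, seq, list(labels))
  out$site_start <- offset
  out$site_end <- offset + site_len
  out
}

#' Dinucleotide-frequency-preserving shuffle
#'
#' Random permutation of a DNA string that keeps the multiset of adjacent
#' nucleotide pairs (and hence mononucleotide counts and the first and last
#' characters) exactly identical, via the Euler-path construction of
#' Altschul and Erickson: the sequence is viewed as an Eulerian walk on the
#' 4-vertex dinucleotide multigraph; a uniformly random last-exit edge set
#' forming an arborescence into the terminal vertex is drawn, the remaining
#' out-edges are permuted, and the walk is re-traversed.
#'
#' Used to produce negative sequences whose low-order composition matches a
#' positive, so a classifier cannot separate the classes on dinucleotide
#' content alone.
#'
#' @param seq DNA string over `A,C,G,T`, length >= 2.
#' @return A shuffled string of the same length.
#' @examples
#' withr::with_seed(7, dinuc_shuffle("ACGTACGTAA"))
#' @export
dinuc_shuffle <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2) abort("dinucleotide shuffle needs length >= 2")
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    abort("dinucleotide shuffle is undefined for non-ACGT characters")
  }
  first <- chars[1]
  last <- chars[n]
  verts <- unique(chars)
  # out-edge target lists of the dinucleotide multigraph
  edges <- split(chars[-1], chars[-n])
  # choose, for every non-terminal vertex with out-edges, a random "last exit"
  # edge; accept when the chosen edges form an arborescence into `last`
  nonterm <- setdiff(names(edges), last)
  repeat {
    last_exit <- vapply(nonterm, function(v) {
      outs <- edges[[v]]
      outs[sample.int(length(outs), 1L)]
    }, character(1))
    ok <- TRUE
    for (v in nonterm) {
      cur <- v
      seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || !(cur %in% names(last_exit))) {
          ok <- FALSE
          break
        }
        seen <- c(seen, cur)
        cur <- last_exit[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute remaining out-edges; pinned last-exit edge goes last
  ordered <- lapply(setNames(names(edges), names(edges)), function(v) {
    outs <- edges[[v]]
    if (v %in% nonterm) {
      pin <- match(last_exit[[v]], outs)
      rest <- outs[-pin]
      c(if (length(rest)) rest[sample.int(length(rest))], outs[pin])
    } else {
      outs[sample.int(length(outs))]
    }
  })
  # walk the Euler path
  out <- character(n)
  out[1] <- first
  ptr <- setNames(rep(1L, length(ordered)), names(ordered))
  cur <- first
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Build a balanced dataset by pairing positives with shuffled negatives
#'
#' For every positive sequence, appends one negative twin produced by
#' [dinuc_shuffle()], carrying all-zero nucleotide labels and sequence label
#' 0, yielding a 1:1 class ratio at the sequence level. At the nucleotide
#' level the classes stay heavily imbalanced (about 15 background labels per
#' binding label for 100-bp windows with 10-15 bp sites). Positives containing
#' `N` are dropped with a warning, since the shuffle (and the 4-letter k-mer
#' vocabulary) is undefined for them.
#'
#' @param positives labeled dataset where every row has `seq_label == 1`.
#' @param seed optional integer seed for the shuffle stream.
#' @return A labeled dataset of `2 * n` rows with a `pair_id` column tying
#'   each positive to its negative (id `"<id>_shuf"`).
#' @examples
#' pos <- withr::with_seed(1, generate_synthetic(synthetic_spec(5, motif = "CAGCTG")))
#' make_dataset(pos, seed = 2)
#' @export
make_dataset <- function(positives, seed = NULL) {
  validate_dataset(positives)
  if (nrow(positives) == 0) {
    out <- positives
    out$pair_id <- character(0)
    return(out)
  }
  if (!all(positives$seq_label == 1L)) abort("all inputs must have seq_label == 1")
  has_n <- grepl("[^ACGT]", positives$seq)
  if (any(has_n)) {
    warn(sprintf("dropping %d positive(s) containing non-ACGT characters: %s",
                 sum(has_n), paste(head(positives$id[has_n], 5), collapse = ", ")))
    positives <- positives[!has_n, , drop = FALSE]
  }
  shuffle_one <- function(pos_id, pos_seq, labels) {
    tibble(
      id = c(pos_id, paste0(pos_id, "_shuf")),
      seq = c(pos_seq, dinuc_shuffle(pos_seq)),
      nuc_labels = list(labels, integer(nchar(pos_seq))),
      seq_label = c(1L, 0L),
      pair_id = c(pos_id, pos_id)
    )
  }
  run <- function() {
    purrr::pmap(
      list(positives$id, positives$seq, positives$nuc_labels),
      shuffle_one
    )
  }
  pairs <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- dplyr::bind_rows(pairs)
  extra <- setdiff(names(positives), names(out))
  # carry any extra columns (e.g. site_start) on the positive rows
  if (length(extra) > 0) {
    out <- dplyr::left_join(out, positives[, c("id", extra)], by = "id")
  }
  validate_dataset(out)
  out
}

#' Split a dataset into training and test partitions, pair-aware
#'
#' Positives and their shuffled twins always land in the same partition, so a
#' model can never see the dinucleotide-shuffled sibling of a test sequence
#' during training. Rows without a `pair_id` are treated as singleton pairs.
#'
#' @param dataset labeled dataset (ideally from [make_dataset()]).
#' @param train_frac fraction of pairs assigned to training (default 0.8).
#' @param seed optional integer seed; the same seed always yields the same
#'   split.
#' @return A list with tibbles `train` and `test`.
#' @export
split_dataset <- function(dataset, train_frac = 0.8, seed = NULL) {
  validate_dataset(dataset)
  if (train_frac <= 0 || train_frac >= 1) abort("train_frac must be in (0, 1)")
  pid <- if ("pair_id" %in% names(dataset)) dataset$pair_id else dataset$id
  pairs <- unique(pid)
  if (length(pairs) < 2) abort("need at least 2 pairs to split")
  n_train <- round(train_frac * length(pairs))
  n_train <- max(1L, min(length(pairs) - 1L, n_train))
  pick <- function() sample(pairs, n_train)
  train_pairs <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  list(
    train = dataset[pid %in% train_pairs, , drop = FALSE],
    test = dataset[!pid %in% train_pairs, , drop = FALSE]
  )
}
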