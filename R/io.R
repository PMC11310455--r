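#' Read a FASTA file of DNA sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases
#' sequences and returns a tibble. Line-wrapped and lowercase records are
#' handled by the underlying parser.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record ids in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(id = ids, seq = unname(toupper(as.character(x))))
}

#' Write sequences to FASTA
#'
#' @param data tibble with `id` and `seq` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  x <- Biostrings::DNAStringSet(setNames(data$seq, data$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write / read a labeled dataset as TSV
#'
#' The on-disk format is one row per sequence with tab-separated fields
#' `id`, `seq`, `nuc_labels` (an unseparated 0/1 string, one digit per
#' nucleotide), `seq_label`, and optionally `pair_id`. `write_labels()` and
#' `read_labels()` are exact inverses.
#'
#' @param dataset labeled dataset tibble.
#' @param path TSV path.
#' @return `write_labels()` returns `path` invisibly; `read_labels()` returns
#'   the dataset tibble.
#' @export
write_labels <- function(dataset, path) {
  validate_dataset(dataset)
  out <- tibble(
    id = dataset$id,
    seq = dataset$seq,
    nuc_labels = vapply(dataset$nuc_labels, paste, "", collapse = ""),
    seq_label = dataset$seq_label
  )
  if ("pair_id" %in% names(dataset)) out$pair_id <- dataset$pair_id
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  bad <- nchar(raw$seq) != nchar(raw$nuc_labels)
  if (any(bad)) {
    abort(paste0("label/sequence length mismatch for record(s): ",
                 paste(head(raw$id[bad], 5), collapse = ", ")))
  }
  labs <- lapply(strsplit(raw$nuc_labels, ""), as.integer)
  out <- labeled_sequences(raw$id, raw$seq, labs, as.integer(raw$seq_label))
  if ("pair_id" %in% names(raw)) out$pair_id <- raw$pair_id
  out
}

#' Read binding-site intervals from a BED3+ file
#'
#' BED uses 0-based half-open coordinates, the package's internal convention.
#' Columns beyond the sixth are ignored; missing name/score/strand columns
#' are filled with defaults.
#'
#' @param path BED file path.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns")
  blank_to <- function(x, default) {
    x <- as.character(x)
    ifelse(is.na(x) | x == "", default, x)
  }
  out <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    name = if (ncol(raw) >= 4) {
      blank_to(raw[[4]], paste0("site_", seq_len(nrow(raw))))
    } else paste0("site_", seq_len(nrow(raw))),
    strand = if (ncol(raw) >= 6) blank_to(raw[[6]], ".") else "."
  )
  if (any(out$start < 0) || any(out$start >= out$end)) {
    abort("invalid interval: require 0 <= start < end")
  }
  out
}

#' Serialize a k-mer vocabulary as plain text
#'
#' One token per line; a token's id is its 0-based line index, following the
#' common BERT vocabulary-file convention.
#'
#' @param vocab a vocabulary from [build_vocab()].
#' @param path output path.
#' @return `path` invisibly / the vocabulary.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  tokens <- readLines(path)
  kmers <- setdiff(tokens, special_tokens())
  k <- unique(nchar(kmers))
  if (length(k) != 1) abort("vocabulary k-mers have inconsistent lengths")
  vocab <- build_vocab(k)
  if (!identical(vocab$tokens, tokens)) {
    abort("vocabulary file does not match canonical token ordering")
  }
  vocab
}

#' Write / read per-nucleotide probability tracks
#'
#' Tracks are TSV with fields `id`, `seq`, `probs` (comma-separated
#' per-nucleotide probabilities), the interchange format between prediction
#' and motif discovery.
#'
#' @param tracks tibble with `id`, `seq` and list-column `probs`.
#' @param path TSV path.
#' @return `path` invisibly / the tracks tibble.
#' @export
write_tracks <- function(tracks, path) {
  out <- tibble(
    id = tracks$id, seq = tracks$seq,
    probs = vapply(tracks$probs, function(p) paste(format(p, digits = 8, trim = TRUE),
                                                   collapse = ","), "")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  probs <- lapply(strsplit(raw$probs, ","), as.numeric)
  bad <- nchar(raw$seq) != lengths(probs)
  if (any(bad)) {
    abort(paste0("probability/sequence length mismatch for record(s): ",
                 paste(head(raw$id[bad], 5), collapse = ", ")))
  }
  tibble(id = raw$id, seq = toupper(raw$seq), probs = probs)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single self-describing archive holding the model
#' configuration, the vocabulary, the named weight arrays, and the training
#' history, so a fitted model can be reloaded without any external context.
#'
#' @param model a fitted model from [tfsnr_fit()].
#' @param path checkpoint path.
#' @return `path` invisibly / the model object.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tfsnr_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  need <- c("weights", "config", "vocab")
  if (!all(need %in% names(obj))) abort("not a model checkpoint")
  structure(obj, class = "tfsnr_model")
}

#' Write a dataset manifest
#'
#' Records provenance of a constructed dataset directory (counts, window
#' length, seed, file names) as YAML.
#'
#' @param dataset labeled dataset.
#' @param path YAML path.
#' @param extra named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path, extra = list()) {
  manifest <- c(list(
    n_records = nrow(dataset),
    n_positive = sum(dataset$seq_label == 1L),
    n_negative = sum(dataset$seq_label == 0L),
    window_len = if (nrow(dataset)) unique(nchar(dataset$seq)) else integer(0),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
  ), extra)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
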