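#' Call binding sites on a per-nucleotide probability track
#'
#' Slides a window of length `window` with stride 1 over the probability
#' track; a window is positive when its chosen statistic (mean by default)
#' is at least `threshold`. Maximal runs of consecutive positive windows are
#' merged, and for each run the central `window`-length region of the run's
#' span is reported as one site (even-length slack resolves to the
#' left-of-center start). Sites are non-overlapping and sorted. Coordinates
#' are 0-based half-open.
#'
#' @param track list/one-row tibble with `seq` and `probs` (equal lengths),
#'   or a bare numeric probability vector.
#' @param window scan window length in bp (default 10).
#' @param threshold confidence threshold in (0, 1) (default 0.5).
#' @param stat window statistic, `"mean"` (default, smooth and monotone) or
#'   `"max"`.
#' @return Tibble with columns `start`, `end` (0-based half-open).
#' @examples
#' p <- rep(0, 30); p[11:18] <- 0.9
#' discover_sites(p, window = 5, threshold = 0.5)
#' @export
discover_sites <- function(track, window = 10L, threshold = 0.5,
                           stat = c("mean", "max")) {
  stat <- match.arg(stat)
  probs <- if (is.numeric(track)) track else track$probs[[1]]
  if (window < 1) abort("window must be >= 1")
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  L <- length(probs)
  if (window > L) abort("window longer than track")
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  n_win <- L - window + 1L
  win_stat <- if (stat == "mean") {
    cs <- c(0, cumsum(probs))
    (cs[(window + 1):(L + 1)] - cs[1:n_win]) / window
  } else {
    vapply(seq_len(n_win), function(s) max(probs[s:(s + window - 1L)]), 0)
  }
  pos <- win_stat >= threshold
  if (!any(pos)) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  r <- rle(pos)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values
  sites <- purrr::map2(run_start[keep], run_end[keep], function(s1, s2) {
    # 0-based span covered by windows s1..s2
    span_start <- s1 - 1L
    span_len <- (s2 - s1) + window
    site_start <- span_start + (span_len - window) %/% 2L
    tibble(start = site_start, end = site_start + window)
  })
  dplyr::bind_rows(sites)
}

#' Extract called site sequences from many tracks
#'
#' Applies [discover_sites()] to every track and pulls out the corresponding
#' DNA substrings. All returned strings have length `window`, so they are
#' already center-aligned and can be stacked directly into a PWM.
#'
#' @param tracks tibble with `id`, `seq`, `probs` (list-column), e.g. a
#'   prediction from [predict.tfsnr_model()] (its `nuc_probs` column is
#'   accepted under either name) or [read_tracks()].
#' @inheritParams discover_sites
#' @return Character vector of site sequences (possibly empty).
#' @export
collect_sites <- function(tracks, window = 10L, threshold = 0.5,
                          stat = c("mean", "max")) {
  stat <- match.arg(stat)
  probs_col <- if ("probs" %in% names(tracks)) tracks$probs else tracks$nuc_probs
  if (is.null(probs_col)) abort("tracks need a `probs` or `nuc_probs` column")
  out <- purrr::map2(tracks$seq, probs_col, function(s, p) {
    sites <- discover_sites(p, window, threshold, stat)
    if (nrow(sites) == 0) return(character(0))
    substring(s, sites$start + 1L, sites$end)
  })
  unlist(out, use.names = FALSE)
}

#' Build a position weight matrix from aligned sites
#'
#' Per-position nucleotide frequencies with an additive pseudocount:
#' `freq[b, j] = (count[b, j] + pseudocount) / (n_sites + 4 * pseudocount)`.
#' Every column sums to 1.
#'
#' @param sites character vector of equal-length DNA strings.
#' @param pseudocount additive smoothing count per base (default 0.01).
#' @return Object of class `tfsnr_pwm`: 4 x width matrix (rows A, C, G, T)
#'   with attribute `n_sites`.
#' @examples
#' build_pwm(rep("CAGCTG", 10), pseudocount = 0)
#' @export
build_pwm <- function(sites, pseudocount = 0.01) {
  if (length(sites) == 0) abort("no sites to build a PWM from")
  w <- unique(nchar(sites))
  if (length(w) != 1) abort("sites must all have the same length")
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(toupper(sites), ""))
  counts <- vapply(seq_len(w), function(j) {
    tabulate(factor(mat[, j], levels = bases), nbins = 4)
  }, numeric(4))
  freqs <- (counts + pseudocount) / (length(sites) + 4 * pseudocount)
  dimnames(freqs) <- list(bases, NULL)
  structure(freqs, n_sites = length(sites), class = c("tfsnr_pwm", "matrix"))
}

#' @export
print.tfsnr_pwm <- function(x, ...) {
  cat(sprintf("<tfsnr_pwm> width %d, built from %d site(s)\n",
              ncol(x), attr(x, "n_sites")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Write a PWM in MEME minimal motif format
#'
#' Emits the standard minimal header (`MEME version 4`, `ALPHABET= ACGT`,
#' background frequencies) and one `MOTIF` block with a
#' `letter-probability matrix` section, the input format of downstream motif
#' comparison tools.
#'
#' @param pwm a [build_pwm()] result (or bare 4 x w column-stochastic
#'   matrix).
#' @param name motif name written in the MOTIF line.
#' @param path output file path.
#' @param background length-4 background frequencies over A, C, G, T.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, name, path,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  check_pwm_matrix(unclass(pwm))
  n_sites <- attr(pwm, "n_sites") %||% 20L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f",
            background[1], background[2], background[3], background[4]),
    "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
            ncol(pwm), n_sites),
    apply(pwm, 2, function(col) sprintf(" %.6f %.6f %.6f %.6f",
                                        col[1], col[2], col[3], col[4]))
  ), con)
  invisible(path)
}

#' Read a MEME minimal motif file
#'
#' Minimal-format reader covering what [write_meme()] emits (one motif per
#' file); used for round-trip checks and for importing reference motifs.
#'
#' @param path MEME file path.
#' @return A `tfsnr_pwm`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^letter-probability matrix:", lines)
  if (length(hdr) != 1) abort("expected exactly one letter-probability matrix")
  w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
  n_sites <- if (grepl("nsites=", lines[hdr])) {
    as.integer(sub(".*nsites= *(\\d+).*", "\\1", lines[hdr]))
  } else NA_integer_
  rows <- lines[(hdr + 1):(hdr + w)]
  vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
  freqs <- t(do.call(rbind, vals))
  rownames(freqs) <- c("A", "C", "G", "T")
  # columns are printed at 6 decimals; renormalize away the rounding residue
  freqs <- sweep(freqs, 2, colSums(freqs), "/")
  check_pwm_matrix(freqs)
  structure(freqs, n_sites = n_sites, class = c("tfsnr_pwm", "matrix"))
}

#' Compare a recovered PWM to the generating PWM
#'
#' Mean per-column Pearson correlation between two PWMs over the central
#' `width` columns of the wider matrix, the recovery statistic for
#' planted-motif experiments where the called window is wider than the true
#' motif.
#'
#' @param pwm_hat recovered PWM (4 x w1).
#' @param pwm_true generating PWM (4 x w2, w2 <= w1).
#' @param shift_search maximum alignment offset searched between the two
#'   (default: all offsets); the best-correlating offset is used.
#' @return Mean per-column Pearson correlation at the best alignment.
#' @export
pwm_recovery_cor <- function(pwm_hat, pwm_true, shift_search = NULL) {
  a <- unclass(pwm_hat)
  b <- unclass(pwm_true)
  if (ncol(a) < ncol(b)) {
    tmp <- a; a <- b; b <- tmp
  }
  offsets <- 0:(ncol(a) - ncol(b))
  if (!is.null(shift_search)) {
    center <- (ncol(a) - ncol(b)) / 2
    offsets <- offsets[abs(offsets - center) <= shift_search]
  }
  best <- -Inf
  for (off in offsets) {
    sub <- a[, (off + 1):(off + ncol(b)), drop = FALSE]
    cc <- mean(vapply(seq_len(ncol(b)), function(j) {
      if (stats::sd(sub[, j]) == 0 || stats::sd(b[, j]) == 0) return(0)
      cor(sub[, j], b[, j])
    }, 0))
    if (cc > best) best <- cc
  }
  best
}
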