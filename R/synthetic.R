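#' Specification for a planted-motif synthetic dataset
#'
#' Describes a simulation that emulates how supervised binding-site data are
#' built from ChIP-seq intervals: every positive example is a fixed-length
#' window containing exactly one binding site at a uniformly random offset,
#' with per-nucleotide 0/1 labels marking the site span. The site itself is
#' drawn either from a position weight matrix, from a fixed consensus string,
#' or — when only a length range is given — from the background model (useful
#' when only the label geometry matters, e.g. for class-imbalance studies).
#'
#' @param n_positives number of positive windows to generate.
#' @param window_len window length in bp (default 100, the conventional
#'   ChIP-seq-derived training window).
#' @param motif either a consensus DNA string, a 4 x w probability matrix
#'   with rownames `A,C,G,T` and columns summing to 1, or `NULL`.
#' @param site_len_range integer `c(min, max)` of site lengths, used only
#'   when `motif` is `NULL`; lengths are drawn uniformly.
#' @param background mononucleotide probability vector over `A,C,G,T`
#'   (default uniform), or a list `list(init =, trans =)` with a 4x4
#'   row-stochastic transition matrix for a first-order (dinucleotide)
#'   background.
#' @param seed integer seed making the whole simulation deterministic.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_synthetic()]
#' @export
synthetic_spec <- function(n_positives, window_len = 100L, motif = NULL,
                           site_len_range = NULL,
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           seed = 1L) {
  if (n_positives < 0) abort("n_positives must be >= 0")
  if (is.character(motif)) {
    motif <- toupper(motif)
    if (!grepl("^[ACGT]+$", motif)) abort("consensus motif must be over ACGT")
    if (nchar(motif) > window_len) abort("site exceeds window")
  } else if (is.matrix(motif)) {
    check_pwm_matrix(motif)
    if (ncol(motif) > window_len) abort("site exceeds window")
  } else if (!is.null(motif)) {
    abort("motif must be a consensus string, a 4 x w matrix, or NULL")
  }
  if (is.null(motif)) {
    if (is.null(site_len_range)) abort("give either a motif or site_len_range")
    site_len_range <- as.integer(site_len_range)
    if (length(site_len_range) != 2 || site_len_range[1] > site_len_range[2] ||
        site_len_range[1] < 1) {
      abort("site_len_range must be c(min, max) with 1 <= min <= max")
    }
    if (site_len_range[2] > window_len) abort("site exceeds window")
  }
  if (is.numeric(background)) {
    if (length(background) != 4 || abs(sum(background) - 1) > 1e-8 ||
        any(background < 0)) {
      abort("background probabilities must be 4 non-negative values summing to 1")
    }
    background <- setNames(as.numeric(background), c("A", "C", "G", "T"))
  } else if (is.list(background)) {
    stopifnot(all(c("init", "trans") %in% names(background)))
    if (any(abs(rowSums(background$trans) - 1) > 1e-8)) {
      abort("background transition rows must sum to 1")
    }
  } else {
    abort("background must be a probability vector or list(init, trans)")
  }
  structure(
    list(n_positives = as.integer(n_positives), window_len = as.integer(window_len),
         motif = motif, site_len_range = site_len_range,
         background = background, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

check_pwm_matrix <- function(m) {
  if (nrow(m) != 4) abort("PWM must have 4 rows (A, C, G, T)")
  if (is.null(rownames(m))) rownames(m) <- c("A", "C", "G", "T")
  if (any(m < 0)) abort("PWM entries must be >= 0")
  if (any(abs(colSums(m) - 1) > 1e-6)) abort("PWM columns must sum to 1")
  invisible(m)
}

# Draw a random background sequence under the spec's background model.
sample_background <- function(n, background) {
  bases <- c("A", "C", "G", "T")
  if (n <= 0) return("")
  if (is.numeric(background)) {
    paste(sample(bases, n, replace = TRUE, prob = background), collapse = "")
  } else {
    out <- character(n)
    out[1] <- sample(bases, 1, prob = background$init)
    if (n > 1) {
      for (i in 2:n) {
        out[i] <- sample(bases, 1, prob = background$trans[out[i - 1], ])
      }
    }
    paste(out, collapse = "")
  }
}

# Draw one site realization from a PWM (column-wise multinomial).
sample_pwm_site <- function(pwm) {
  bases <- rownames(pwm)
  paste(vapply(seq_len(ncol(pwm)), function(j) {
    sample(bases, 1, prob = pwm[, j])
  }, character(1)), collapse = "")
}

#' Generate a planted-motif positive set
#'
#' Realizes a [synthetic_spec()]: `n_positives` windows, each containing one
#' site at a uniformly random offset, labels 1 exactly on the site. The
#' ground-truth motif is attached as attribute `truth_pwm` (a one-hot PWM for
#' a consensus motif, `NULL` for background-drawn sites) so recovery
#' experiments can compare an inferred PWM against the generating one.
#' Deterministic for a fixed spec (the seed lives in the spec).
#'
#' @param spec a [synthetic_spec()].
#' @return A labeled dataset (see [labeled_sequences()]) with columns
#'   `site_start`/`site_end`, and attribute `truth_pwm`.
#' @examples
#' pos <- generate_synthetic(synthetic_spec(3, motif = "CAGCTG", seed = 9))
#' pos$site_start
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- NULL
  if (is.character(spec$motif)) {
    truth <- consensus_pwm(spec$motif)
  } else if (is.matrix(spec$motif)) {
    truth <- spec$motif
  }
  if (spec$n_positives == 0L) {
    out <- labeled_sequences(character(0), character(0), list())
    out$site_start <- integer(0)
    out$site_end <- integer(0)
    attr(out, "truth_pwm") <- truth
    return(out)
  }
  gen <- function() {
    rows <- lapply(seq_len(spec$n_positives), function(i) {
      site <- if (is.character(spec$motif)) {
        spec$motif
      } else if (is.matrix(spec$motif)) {
        sample_pwm_site(spec$motif)
      } else {
        len <- sample(seq(spec$site_len_range[1], spec$site_len_range[2]), 1)
        sample_background(len, spec$background)
      }
      extract_window(
        site,
        left_flank = sample_background(spec$window_len, spec$background),
        right_flank = sample_background(spec$window_len, spec$background),
        window_len = spec$window_len,
        id = sprintf("synth_%05d", i)
      )
    })
    dplyr::bind_rows(rows)
  }
  out <- withr::with_seed(substream_seed(spec$seed, "synthetic"), gen())
  attr(out, "truth_pwm") <- truth
  out
}

# One-hot PWM for a consensus string.
consensus_pwm <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  m <- matrix(0, 4, length(chars), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(chars)) m[chars[j], j] <- 1
  m
}
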