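#' Describe how k-mers are drawn from nucleotide sequences
#'
#' A `kmer_spec` fixes the three choices that every k-mer operation in the
#' package must agree on: the word length `k`, whether each k-mer is folded
#' with its reverse complement onto the lexicographically smaller of the two
#' (canonical k-mers, making indexing and query strand-agnostic), and how
#' windows containing non-ACGT symbols are treated. Both partner indexes and
#' all query-side window extraction must share one spec; mixing specs is an
#' error everywhere downstream.
#'
#' The default `k = 25` suits short-read meta-transcriptomes that may contain
#' 50-bp reads: it is small enough that such reads still contribute a few
#' dozen windows, while long enough that a match is close to read-specific.
#' `canonical = TRUE` by default because RNA-seq libraries are frequently
#' unstranded; set `canonical = FALSE` for stranded protocols.
#'
#' @param k Positive integer word length in bases (`k >= 2`).
#' @param canonical Fold each k-mer with its reverse complement
#'   (lexicographic minimum of the two)?
#' @param alphabet_policy How windows containing symbols outside `{A,C,G,T}`
#'   are handled. Only `"skip"` is implemented: such windows are silently
#'   omitted, the behaviour of standard k-mer counters.
#' @return An object of class `kmer_spec`.
#' @examples
#' kmer_spec(k = 25)
#' kmer_spec(k = 5, canonical = FALSE)
#' @export
kmer_spec <- function(k = 25L, canonical = TRUE, alphabet_policy = "skip") {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 2L) {
    abort("`k` must be a single integer >= 2.", class = "holosort_parameter_error")
  }
  if (!rlang::is_bool(canonical)) {
    abort("`canonical` must be TRUE or FALSE.", class = "holosort_parameter_error")
  }
  alphabet_policy <- match.arg(alphabet_policy, "skip")
  structure(
    list(k = k, canonical = canonical, alphabet_policy = alphabet_policy),
    class = "kmer_spec"
  )
}

#' @export
print.kmer_spec <- function(x, ...) {
  cat(sprintf(
    "<kmer_spec> k = %d, %s, non-ACGT windows: %s\n",
    x$k, if (x$canonical) "canonical (strand-folded)" else "stranded",
    x$alphabet_policy
  ))
  invisible(x)
}

#' @export
format.kmer_spec <- function(x, ...) {
  sprintf("k=%d/%s", x$k, if (x$canonical) "canonical" else "stranded")
}

specs_identical <- function(a, b) {
  identical(a$k, b$k) && identical(a$canonical, b$canonical) &&
    identical(a$alphabet_policy, b$alphabet_policy)
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over plain character vectors (A<->T, C<->G,
#' case preserved). Used throughout for canonical folding; exposed because
#' the simulator and tests need it too.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", stringi::stri_reverse(x))
}

#' Fold k-mers onto their canonical form
#'
#' Returns, element-wise, the lexicographically smaller of each k-mer and its
#' reverse complement. Comparison is over the ACGT alphabet in C collation.
#'
#' @param kmers Character vector of uppercase ACGT k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonicalize <- function(kmers) {
  if (length(kmers) == 0L) return(character())
  rc <- revcomp(kmers)
  smaller <- stringi::stri_cmp_lt(kmers, rc, locale = "C")
  ifelse(smaller | kmers == rc, kmers, rc)
}

# All fixed-length windows of `sequence`, with 0-based starts, invalid
# (non-ACGT) windows dropped, canonical folding applied per `spec`.
# Workhorse behind extract_kmers(); returns a bare list to avoid tibble
# overhead on hot paths.
window_kmers <- function(sequence, spec) {
  seq_up <- toupper(sequence)
  n <- nchar(seq_up)
  k <- spec$k
  if (is.na(n) || n < k) {
    return(list(start = integer(), kmer = character()))
  }
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq_up, starts, starts + k - 1L)
  ok <- !stringi::stri_detect_regex(kmers, "[^ACGT]")
  starts <- starts[ok]
  kmers <- kmers[ok]
  if (spec$canonical) kmers <- canonicalize(kmers)
  list(start = starts - 1L, kmer = kmers)
}

#' Extract k-mers and their positions from a sequence
#'
#' Slides a window of length `k` over `sequence` left to right and returns
#' one row per window made exclusively of A, C, G, T. Windows containing any
#' other symbol (N, IUPAC ambiguity codes, gaps) are skipped. With a
#' canonical spec each k-mer is replaced by the smaller of itself and its
#' reverse complement; the start position always refers to the window on the
#' input strand.
#'
#' @param sequence A single nucleotide string.
#' @param spec A [kmer_spec()].
#' @return A tibble with columns `start` (0-based window start, strictly
#'   increasing) and `kmer`. Sequences shorter than `k` (or empty) give zero
#'   rows, not an error.
#' @examples
#' extract_kmers("ACGT", kmer_spec(k = 2, canonical = FALSE))
#' extract_kmers("ACNGT", kmer_spec(k = 2, canonical = FALSE))
#' @export
extract_kmers <- function(sequence, spec = kmer_spec()) {
  stopifnot(inherits(spec, "kmer_spec"))
  if (length(sequence) != 1L || !is.character(sequence)) {
    abort("`sequence` must be a single string.", class = "holosort_parameter_error")
  }
  w <- window_kmers(sequence, spec)
  tibble(start = w$start, kmer = w$kmer)
}
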