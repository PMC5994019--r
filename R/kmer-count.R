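#' Count k-mer occurrences across a sequence bank
#'
#' Exact in-process k-mer counter: every valid window of every sequence is
#' extracted (canonicalised per the spec) and tallied. The count of a k-mer
#' is its total number of occurrences across the whole bank, so duplicated
#' sequences double counts. This is the abundance table that the solidity
#' filter consumes.
#'
#' @param bank Sequences of one reference library: a character vector, a
#'   tibble with a `sequence` column (as returned by [read_sequences()]), or
#'   a `Biostrings::DNAStringSet`.
#' @param spec A [kmer_spec()].
#' @return A tibble with columns `kmer` and `count`, sorted by `kmer`.
#' @examples
#' count_kmers("ACGT", kmer_spec(k = 2, canonical = FALSE))
#' @export
count_kmers <- function(bank, spec = kmer_spec()) {
  stopifnot(inherits(spec, "kmer_spec"))
  seqs <- as_sequence_vector(bank)
  if (length(seqs) == 0L) {
    return(tibble(kmer = character(), count = integer()))
  }
  all_kmers <- unlist(
    lapply(seqs, function(s) window_kmers(s, spec)$kmer),
    use.names = FALSE
  )
  if (length(all_kmers) == 0L) {
    return(tibble(kmer = character(), count = integer()))
  }
  tbl <- table(all_kmers)
  tibble(kmer = names(tbl), count = as.integer(tbl)) |> arrange(.data$kmer)
}

#' Keep the solid k-mers of an abundance table
#'
#' Solid k-mers are those whose occurrence count in the bank reaches the
#' solidity threshold; rarer k-mers are presumed to carry sequencing errors
#' and are dropped. For banks of raw short reads with appreciable coverage a
#' threshold of 2 removes most error k-mers; for assembled transcripts,
#' genes or ESTs every k-mer is taken at face value and the threshold is 1
#' (with threshold 1 the solid set is exactly the set of distinct k-mers of
#' the bank).
#'
#' @param counts Abundance tibble from [count_kmers()] (columns `kmer`,
#'   `count`).
#' @param solidity_threshold Minimum occurrence count, integer `>= 1`.
#' @param spec The [kmer_spec()] the counts were produced under.
#' @param source_label Free-text bank name carried into reports (e.g.
#'   `"host"`).
#' @return A `solid_kmer_set`: list with `kmers` (character), `count`
#'   (integer abundances), `spec`, `solidity_threshold`, `source_label`.
#' @examples
#' counts <- count_kmers(c("ACGTA", "ACGTC"), kmer_spec(k = 4, canonical = FALSE))
#' solid_filter(counts, 2, kmer_spec(k = 4, canonical = FALSE))
#' @export
solid_filter <- function(counts, solidity_threshold = 2L,
                         spec = kmer_spec(), source_label = "bank") {
  solidity_threshold <- as.integer(solidity_threshold)
  if (length(solidity_threshold) != 1L || is.na(solidity_threshold) ||
      solidity_threshold < 1L) {
    abort("`solidity_threshold` must be a single integer >= 1.",
          class = "holosort_parameter_error")
  }
  stopifnot(is.data.frame(counts), all(c("kmer", "count") %in% names(counts)))
  keep <- counts$count >= solidity_threshold
  structure(
    list(
      kmers = counts$kmer[keep],
      count = as.integer(counts$count[keep]),
      spec = spec,
      solidity_threshold = solidity_threshold,
      source_label = source_label
    ),
    class = "solid_kmer_set"
  )
}

#' @export
print.solid_kmer_set <- function(x, ...) {
  cat(sprintf(
    "<solid_kmer_set> '%s': %d solid k-mers (%s, solidity >= %d)\n",
    x$source_label, length(x$kmers), format(x$spec), x$solidity_threshold
  ))
  invisible(x)
}

# Coerce the accepted bank representations to a plain character vector.
as_sequence_vector <- function(bank) {
  if (is.character(bank)) return(bank)
  if (is.data.frame(bank)) {
    if (!"sequence" %in% names(bank)) {
      abort("A data-frame bank needs a `sequence` column.",
            class = "holosort_parameter_error")
    }
    return(as.character(bank$sequence))
  }
  if (inherits(bank, "XStringSet")) return(as.character(bank))
  abort("Unsupported bank type; supply a character vector, a tibble with a `sequence` column, or a DNAStringSet.",
        class = "holosort_parameter_error")
}
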