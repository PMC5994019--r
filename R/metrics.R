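#' N50 of a set of contig lengths
#'
#' The N50 is the largest contig length `L` present in the set such that
#' contigs of length `>= L` together contain at least half of all assembled
#' bases. Conventions differ subtly between tools around ties and the
#' half-way parity; this package uses exactly the rule above (equivalently:
#' sort lengths in decreasing order, accumulate, and report the length at
#' which the running total first reaches half the grand total).
#'
#' @param lengths Non-negative integer vector of contig lengths.
#' @return The N50 in bases; `0` for an empty set.
#' @examples
#' n50(c(6, 5, 4, 3, 2))  # total 20; 6+5 = 11 >= 10, so N50 = 5
#' @export
n50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L || sum(lengths) == 0) return(0)
  sorted <- sort(lengths, decreasing = TRUE)
  sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1L]]
}

#' Assembly summary metrics of a contig set
#'
#' Computes the contig-level statistics customarily reported per assembly:
#' contig count, smallest/longest/mean length, N50 (see [n50()]) and GC
#' content. GC is computed over A, C, G, T bases only, pooled across all
#' contigs; ambiguity symbols are excluded from both numerator and
#' denominator.
#'
#' @param contigs Contig sequences: tibble with a `sequence` column,
#'   character vector, `DNAStringSet`, or a FASTA file path.
#' @return A one-row tibble with `n_contigs`, `total_bases`, `smallest`,
#'   `longest`, `mean_length`, `n50`, `gc_percent`. An empty set gives all
#'   zeros.
#' @export
contig_metrics <- function(contigs) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs)) {
    contigs <- read_sequences(contigs)
  }
  seqs <- as_sequence_vector(contigs)
  if (length(seqs) == 0L) {
    return(tibble(
      n_contigs = 0L, total_bases = 0, smallest = 0, longest = 0,
      mean_length = 0, n50 = 0, gc_percent = 0
    ))
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  gc <- sum(stringi::stri_count_regex(seqs, "[GC]"))
  acgt <- sum(stringi::stri_count_regex(seqs, "[ACGT]"))
  tibble(
    n_contigs = length(seqs),
    total_bases = sum(lens),
    smallest = min(lens),
    longest = max(lens),
    mean_length = mean(lens),
    n50 = n50(lens),
    gc_percent = if (acgt > 0) 100 * gc / acgt else 0
  )
}

#' Render partition, assembly and chimera results as report tables
#'
#' Produces the publication-style text blocks: the per-category read
#' assignment table (counts plus percentages at two decimals), optionally a
#' per-category assembly-metrics block, a chimera summary line, and the
#' per-round history when the partition came from iterative enrichment.
#' A TSV copy of each block can be written alongside.
#'
#' @param partition A `read_partition` or `enrichment_result`, or the tidy
#'   report tibble itself.
#' @param per_category_metrics Optional tibble of [contig_metrics()] rows
#'   with a leading `category` column.
#' @param chimera_summary Optional one-row tibble from
#'   `glance(<chimera_screen>)`.
#' @param path Optional directory; when given, each block is also written
#'   as `partition.tsv` / `assembly_metrics.tsv` / `chimera.tsv` there.
#' @return The rendered report as a character vector of lines (invisibly
#'   printed with `cat()` friendliness).
#' @export
render_reports <- function(partition, per_category_metrics = NULL,
                           chimera_summary = NULL, path = NULL) {
  report <- if (inherits(partition, "enrichment_result")) {
    partition$partition$report
  } else if (inherits(partition, "read_partition")) {
    partition$report
  } else {
    stopifnot(is.data.frame(partition))
    partition
  }
  history <- if (inherits(partition, "enrichment_result")) partition$history else NULL

  fmt_block <- function(df) {
    df <- mutate(df, across(dplyr::where(is.numeric), ~ round(.x, 2)))
    utils::capture.output(print(as.data.frame(df), row.names = FALSE))
  }
  total <- sum(report$n_reads)
  part_tbl <- report |>
    select("category", "n_reads", "percent") |>
    mutate(percent = sprintf("%.2f", .data$percent))
  lines <- c(
    "== Read assignment ==",
    fmt_block(part_tbl),
    sprintf("Total %d", total)
  )
  if (!is.null(history)) {
    lines <- c(lines, "", "== Enrichment rounds ==",
               fmt_block(select(history, "round", "category", "n_reads", "percent")))
  }
  if (!is.null(per_category_metrics)) {
    lines <- c(lines, "", "== Assembly metrics ==", fmt_block(per_category_metrics))
  }
  if (!is.null(chimera_summary)) {
    lines <- c(lines, "", "== Chimera screen ==",
               sprintf("n_contigs %d  n_chimera %d  fraction %.3f%%",
                       chimera_summary$n_contigs, chimera_summary$n_chimera,
                       100 * chimera_summary$fraction_chimera))
  }
  if (!is.null(path)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(report, file.path(path, "partition.tsv"))
    if (!is.null(history)) readr::write_tsv(history, file.path(path, "rounds.tsv"))
    if (!is.null(per_category_metrics)) {
      readr::write_tsv(per_category_metrics, file.path(path, "assembly_metrics.tsv"))
    }
    if (!is.null(chimera_summary)) {
      readr::write_tsv(chimera_summary, file.path(path, "chimera.tsv"))
    }
  }
  lines
}
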