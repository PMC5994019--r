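#' Iteratively enrich incomplete reference libraries with recruited reads
#'
#' When a partner's reference library is incomplete, reads from the missing
#' transcripts fall into the unassigned category. Enrichment exploits the
#' reads themselves: after a classification round, reads assigned
#' *exclusively* to one partner are appended to that partner's bank, the
#' indexes are rebuilt, and the whole read set is classified again. Reads
#' bridging indexed and unindexed regions of a transcript seed the recovery
#' of their neighbours, so successive rounds assign more reads. Shared reads
#' are added to neither bank — a conservative choice that prevents
#' cross-contamination feedback between the partner libraries.
#'
#' Because a round can only add k-mers to each index, per-read coverage
#' fractions never decrease across rounds, hence the unassigned count is
#' non-increasing. The loop stops when a round recruits fewer than
#' `min_new_reads` new partner-assigned reads, or after `max_rounds`.
#' With `max_rounds = 1` the result is exactly a single [partition_reads()]
#' pass.
#'
#' @inheritParams classify_reads
#' @param host_bank,symbiont_bank Reference sequences for each partner
#'   (character vector, tibble with `sequence`, or `DNAStringSet`).
#' @param spec Shared [kmer_spec()] for both banks.
#' @param solidity_host,solidity_symbiont Solidity thresholds used when
#'   (re)building each index; the same threshold is applied in every round.
#' @param max_rounds Maximum number of classification rounds, `>= 1`.
#' @param min_new_reads Stop when a round newly assigns fewer reads than
#'   this to the two partner categories combined.
#' @return An `enrichment_result`: `$partition` (final [partition_reads()]
#'   result), `$history` (per-round category counts, a tibble), `$rounds`.
#'   `tidy()` returns the history; `glance()` the final round summary.
#' @export
iterative_enrich <- function(reads, host_bank, symbiont_bank,
                             spec = kmer_spec(), s_percent = 50,
                             solidity_host = 1L, solidity_symbiont = 1L,
                             max_rounds = 3L, min_new_reads = 1L,
                             coverage_mode = c("span", "start"),
                             denominator = c("read_length", "window_count")) {
  max_rounds <- as.integer(max_rounds)
  if (is.na(max_rounds) || max_rounds < 1L) {
    abort("`max_rounds` must be >= 1.", class = "holosort_parameter_error")
  }
  coverage_mode <- match.arg(coverage_mode)
  denominator <- match.arg(denominator)
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read_", seq_along(reads)), sequence = reads)
  }
  host_seqs <- as_sequence_vector(host_bank)
  sym_seqs <- as_sequence_vector(symbiont_bank)

  recruit_host <- character()
  recruit_sym <- character()
  history <- list()
  partition <- NULL
  prev_assigned <- 0L

  for (round in seq_len(max_rounds)) {
    host_idx <- index_bank(c(host_seqs, recruit_host), spec,
                           solidity_threshold = solidity_host,
                           source_label = "host")
    sym_idx <- index_bank(c(sym_seqs, recruit_sym), spec,
                          solidity_threshold = solidity_symbiont,
                          source_label = "symbiont")
    partition <- partition_reads(reads, host_idx, sym_idx,
                                 s_percent = s_percent,
                                 coverage_mode = coverage_mode,
                                 denominator = denominator)
    rep <- partition$report
    n_host <- rep$n_reads[rep$category == "host"]
    n_sym <- rep$n_reads[rep$category == "symbiont"]
    assigned <- n_host + n_sym
    new_reads <- assigned - prev_assigned
    history[[round]] <- rep |> mutate(round = round, .before = 1L)
    # recruits accumulate over rounds (exclusive partner assignments only)
    a <- partition$assignments
    recruit_host <- unique(c(recruit_host, a$sequence[a$category == "host"]))
    recruit_sym <- unique(c(recruit_sym, a$sequence[a$category == "symbiont"]))
    if (round > 1L && new_reads < min_new_reads) break
    prev_assigned <- assigned
  }

  structure(
    list(
      partition = partition,
      history = bind_rows(history),
      rounds = length(history)
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d round(s)\n", x$rounds))
  hist <- x$history |>
    tidyr::pivot_wider(id_cols = "round", names_from = "category",
                       values_from = "n_reads")
  print(as.data.frame(hist), row.names = FALSE)
  invisible(x)
}

#' @rdname iterative_enrich
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) x$history

#' @rdname iterative_enrich
#' @export
glance.enrichment_result <- function(x, ...) {
  glance(x$partition) |> mutate(rounds = x$rounds)
}
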