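#' Position-coverage similarity of one read against a bank index
#'
#' The similarity of a read to a reference bank is the fraction of the
#' read's positions covered by indexed k-mers. Two coverage semantics are
#' offered:
#'
#' * `"span"` (default): a 0-based position `p` of the read counts as
#'   covered when at least one window `[q, q + k)` with an indexed k-mer
#'   contains it — overlapping or non-overlapping matching k-mers each
#'   cover their whole footprint. A read of length `l` is similar to the
#'   bank when at least `l * s/100` positions are covered.
#' * `"start"`: only the number of window starts whose k-mer is indexed is
#'   counted.
#'
#' The denominator of the reported fraction is the read length `l` by
#' default, or the window count `l - k + 1`. The measure is asymmetric by
#' design: it depends on where matching k-mers fall on the *query* read,
#' not on their layout in the bank.
#'
#' @param read A single nucleotide string (or a one-row tibble with a
#'   `sequence` column).
#' @param index A `bank_index`.
#' @param coverage_mode `"span"` or `"start"`.
#' @param denominator `"read_length"` or `"window_count"`.
#' @return A one-row tibble with `covered` (integer), `fraction`
#'   (in `[0, 1]` under the default denominator) and `too_short` (`TRUE`
#'   when `l < k`, in which case `covered = 0`, `fraction = 0`, no error).
#' @export
coverage_similarity <- function(read, index,
                                coverage_mode = c("span", "start"),
                                denominator = c("read_length", "window_count")) {
  coverage_mode <- match.arg(coverage_mode)
  denominator <- match.arg(denominator)
  seqs <- as_sequence_vector(read)
  if (length(seqs) != 1L) {
    abort("`read` must be a single sequence.", class = "holosort_parameter_error")
  }
  cov <- batch_coverage(seqs, index, coverage_mode, denominator)
  tibble(covered = cov$covered, fraction = cov$fraction, too_short = cov$too_short)
}

# Vectorised coverage of many reads against one index. One membership query
# over the concatenated windows of the whole batch, then per-read interval
# union (span) or hit count (start).
batch_coverage <- function(seqs, index, coverage_mode, denominator) {
  k <- index$spec$k
  n <- length(seqs)
  lens <- nchar(seqs)
  too_short <- lens < k
  covered <- integer(n)
  if (any(!too_short)) {
    wins <- lapply(seqs[!too_short], window_kmers, spec = index$spec)
    nwin <- vapply(wins, function(w) length(w$kmer), integer(1L))
    member <- contains_core(index, unlist(lapply(wins, `[[`, "kmer"), use.names = FALSE))
    member_by_read <- split(member, rep.int(seq_along(wins), nwin))
    idx_live <- which(!too_short)
    for (j in seq_along(wins)) {
      m <- member_by_read[[as.character(j)]]
      if (is.null(m) || !any(m)) next
      hits <- wins[[j]]$start[m]  # 0-based
      i <- idx_live[j]
      if (coverage_mode == "start") {
        covered[i] <- length(hits)
      } else {
        l <- lens[i]
        # sweep over 1-based positions: window [q, q+k) opens at q+1 and
        # stops covering after q+k, so subtract its close at q+k+1
        opens <- tabulate(hits + 1L, nbins = l)
        closes <- tabulate(hits + k + 1L, nbins = l + 1L)[seq_len(l)]
        covered[i] <- sum(cumsum(opens - closes) > 0L)
      }
    }
  }
  denom <- if (denominator == "read_length") lens else pmax.int(lens - k + 1L, 1L)
  fraction <- ifelse(too_short | denom == 0L, 0, covered / denom)
  list(covered = covered, fraction = fraction, too_short = too_short)
}

new_classifier_config <- function(s_percent, coverage_mode, denominator, pair_policy) {
  if (!is.numeric(s_percent) || length(s_percent) != 1L ||
      is.na(s_percent) || s_percent < 0 || s_percent > 100) {
    abort("`s_percent` must be a single number in [0, 100].",
          class = "holosort_parameter_error")
  }
  list(
    s_percent = as.numeric(s_percent),
    coverage_mode = match.arg(coverage_mode, c("span", "start")),
    denominator = match.arg(denominator, c("read_length", "window_count")),
    pair_policy = match.arg(pair_policy, c("independent", "union", "intersection"))
  )
}

category_levels <- c("host", "symbiont", "shared", "unassigned")

#' Classify holobiont reads against host and symbiont indexes
#'
#' Each read is scored against both partner banks with
#' [coverage_similarity()] and routed to exactly one category. A read is
#' *similar* to a bank when its coverage fraction reaches `s_percent / 100`
#' (inclusive boundary: "at least" that many positions). Similar to the host
#' only gives `host`; to the symbiont only, `symbiont`; to both, `shared`;
#' to neither — including every read shorter than `k` — `unassigned`. The
#' four categories are therefore pairwise disjoint and exhaustive.
#'
#' @param reads Tibble with `read_id` and `sequence` columns (see
#'   [read_sequences()]), or a character vector of sequences.
#' @param host_index,symbiont_index `bank_index` objects built under an
#'   identical [kmer_spec()] (checked; mismatch is a configuration error).
#' @param s_percent Similarity threshold in percent of positions, `[0, 100]`.
#' @inheritParams coverage_similarity
#' @return The input tibble with columns `covered_host`, `fraction_host`,
#'   `covered_symbiont`, `fraction_symbiont`, `too_short` and `category`
#'   (factor with levels host, symbiont, shared, unassigned) appended.
#' @export
classify_reads <- function(reads, host_index, symbiont_index, s_percent = 50,
                           coverage_mode = c("span", "start"),
                           denominator = c("read_length", "window_count")) {
  cfg <- new_classifier_config(s_percent, coverage_mode, denominator, "independent")
  stopifnot(inherits(host_index, "bank_index"), inherits(symbiont_index, "bank_index"))
  if (!specs_identical(host_index$spec, symbiont_index$spec)) {
    abort("Host and symbiont indexes were built under different k-mer specs.",
          class = "holosort_config_error")
  }
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read_", seq_along(reads)), sequence = reads)
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  seqs <- as.character(reads$sequence)
  if (any(!nzchar(seqs) | is.na(seqs))) {
    bad <- which(!nzchar(seqs) | is.na(seqs))[1L]
    abort(sprintf("Read record %d ('%s') has an empty sequence.",
                  bad, reads$read_id[bad]),
          class = "holosort_input_error")
  }
  ch <- batch_coverage(seqs, host_index, cfg$coverage_mode, cfg$denominator)
  cs <- batch_coverage(seqs, symbiont_index, cfg$coverage_mode, cfg$denominator)
  thr <- cfg$s_percent / 100
  sim_h <- !ch$too_short & ch$fraction >= thr
  sim_s <- !cs$too_short & cs$fraction >= thr
  reads |>
    mutate(
      covered_host = ch$covered,
      fraction_host = ch$fraction,
      covered_symbiont = cs$covered,
      fraction_symbiont = cs$fraction,
      too_short = ch$too_short,
      category = factor(
        dplyr::case_when(
          sim_h & !sim_s ~ "host",
          !sim_h & sim_s ~ "symbiont",
          sim_h & sim_s ~ "shared",
          .default = "unassigned"
        ),
        levels = category_levels
      )
    )
}

#' Partition a holobiont read set into the four categories
#'
#' Runs [classify_reads()] and wraps the result in a `read_partition`
#' object carrying the per-category report. When `outdir` is given, the
#' reads of each category are written to
#' `<outdir>/<prefix><category>.<ext>` (FASTQ when the input carries
#' qualities, FASTA otherwise, unless forced) so each subset can be
#' assembled independently; every input read lands in exactly one file.
#'
#' @inheritParams classify_reads
#' @param outdir Optional output directory for the four category files
#'   (created if needed).
#' @param format `"auto"`, `"fasta"` or `"fastq"` for the category files.
#' @param prefix Filename prefix for category files.
#' @param gzip Compress category files?
#' @return A `read_partition`: use `tidy()` for the per-category count/
#'   percent report (the shape of a published assignment table), `glance()`
#'   for a one-row run summary, `autoplot()` for a category bar chart, and
#'   `$assignments` for the full per-read tibble.
#' @export
partition_reads <- function(reads, host_index, symbiont_index, s_percent = 50,
                            coverage_mode = c("span", "start"),
                            denominator = c("read_length", "window_count"),
                            outdir = NULL, format = c("auto", "fasta", "fastq"),
                            prefix = "", gzip = FALSE) {
  format <- match.arg(format)
  assignments <- classify_reads(reads, host_index, symbiont_index,
                                s_percent = s_percent,
                                coverage_mode = coverage_mode,
                                denominator = denominator)
  report <- partition_report(assignments)
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    has_qual <- "quality" %in% names(assignments) && any(!is.na(assignments$quality))
    fmt <- switch(format, auto = if (has_qual) "fastq" else "fasta", format)
    ext <- paste0(".", if (fmt == "fastq") "fastq" else "fasta", if (gzip) ".gz" else "")
    files <- setNames(
      file.path(outdir, paste0(prefix, category_levels, ext)),
      category_levels
    )
    for (cat in category_levels) {
      sub <- assignments |> filter(.data$category == cat)
      # write-to-temp + rename keeps a failed run from leaving partial files
      tmp <- paste0(files[[cat]], ".tmp")
      write_sequences(sub, tmp, format = fmt)
      file.rename(tmp, files[[cat]])
    }
  }
  structure(
    list(
      assignments = assignments,
      report = report,
      files = files,
      params = list(
        k = host_index$spec$k,
        canonical = host_index$spec$canonical,
        s_percent = as.numeric(s_percent),
        coverage_mode = match.arg(coverage_mode),
        denominator = match.arg(denominator),
        solidity_host = host_index$solidity_threshold,
        solidity_symbiont = symbiont_index$solidity_threshold,
        index_mode = host_index$mode
      )
    ),
    class = "read_partition"
  )
}

# Per-category counts and percentages from an assignment tibble.
partition_report <- function(assignments) {
  total <- nrow(assignments)
  tab <- table(assignments$category)
  tibble(
    category = factor(category_levels, levels = category_levels),
    n_reads = as.integer(tab[category_levels]),
    percent = if (total > 0) as.numeric(100 * tab[category_levels] / total) else rep(0, 4L),
    n_too_short = as.integer(tapply(
      assignments$too_short, assignments$category, sum, default = 0L
    )[category_levels])
  )
}

#' @export
print.read_partition <- function(x, ...) {
  cat(sprintf("<read_partition> %d reads (k = %d, s = %g%%, %s coverage)\n",
              nrow(x$assignments), x$params$k, x$params$s_percent,
              x$params$coverage_mode))
  rep <- x$report |> mutate(percent = sprintf("%.2f", .data$percent))
  print(as.data.frame(rep), row.names = FALSE)
  invisible(x)
}

#' @rdname partition_reads
#' @param x A `read_partition`.
#' @param ... Unused.
#' @export
tidy.read_partition <- function(x, ...) x$report

#' @rdname partition_reads
#' @export
glance.read_partition <- function(x, ...) {
  counts <- setNames(as.list(x$report$n_reads), paste0("n_", x$report$category))
  as_tibble(c(
    list(total_reads = nrow(x$assignments)),
    counts,
    list(n_too_short = sum(x$assignments$too_short)),
    x$params[c("k", "s_percent", "coverage_mode")]
  ))
}

#' Reconcile the categories of a read pair
#'
#' Mates are classified independently by default (counts are per read, not
#' per fragment). Two joint policies are available for paired libraries:
#' `"union"` propagates any partner assignment across the pair — a pair with
#' one host and one symbiont mate (or any shared mate) becomes shared, a
#' partner label plus an unassigned mate becomes that partner; under
#' `"intersection"` a pair keeps a label only when both mates already agree,
#' and disagreeing pairs become unassigned.
#'
#' @param cat1,cat2 Category vectors (character or factor) of mate 1 and
#'   mate 2, parallel.
#' @param policy `"independent"`, `"union"` or `"intersection"`.
#' @return A tibble with columns `mate1` and `mate2`, the reconciled
#'   categories (always equal to each other under `union`/`intersection`).
#' @export
reconcile_pairs <- function(cat1, cat2,
                            policy = c("independent", "union", "intersection")) {
  policy <- match.arg(policy)
  cat1 <- as.character(cat1)
  cat2 <- as.character(cat2)
  stopifnot(length(cat1) == length(cat2),
            all(c(cat1, cat2) %in% category_levels))
  if (policy == "independent") {
    out1 <- cat1
    out2 <- cat2
  } else if (policy == "union") {
    has_h <- cat1 %in% c("host", "shared") | cat2 %in% c("host", "shared")
    has_s <- cat1 %in% c("symbiont", "shared") | cat2 %in% c("symbiont", "shared")
    joint <- dplyr::case_when(
      has_h & has_s ~ "shared",
      has_h ~ "host",
      has_s ~ "symbiont",
      .default = "unassigned"
    )
    out1 <- out2 <- joint
  } else {
    joint <- ifelse(cat1 == cat2, cat1, "unassigned")
    out1 <- out2 <- joint
  }
  tibble(
    mate1 = factor(out1, levels = category_levels),
    mate2 = factor(out2, levels = category_levels)
  )
}
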