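HIT_COLUMNS <- c("query_id", "subject_id", "pident", "length", "mismatches",
                 "gapopens", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Parse a 12-column tabular alignment file of translated-search hits
#'
#' Reads the standard 12-column tabular dialect (query, subject, %identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bit score — BLAST `-outfmt 6` and equivalents). Rows with
#' e-value above `evalue_max` are discarded, and reverse-orientation query
#' coordinates are normalised so `query_start <= query_end`. Each retained
#' row is labelled with the partner reference it was searched against.
#'
#' @param path Path to the tabular hit file (lines starting with `#` are
#'   ignored).
#' @param partner_label `"host"` or `"symbiont"`.
#' @param evalue_max E-value cut-off; hits above it are dropped (default
#'   1e-3, the customary screening stringency).
#' @return A tibble of hits with columns `query_id`, `partner_label`,
#'   `query_start`, `query_end`, `evalue`, `bitscore` (plus the subject
#'   coordinates), sorted as encountered.
#' @export
parse_hits <- function(path, partner_label = c("host", "symbiont"),
                       evalue_max = 1e-3) {
  partner_label <- match.arg(partner_label)
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    abort("`evalue_max` must be > 0.", class = "holosort_parameter_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("Hit file not found: '%s'", path), class = "holosort_io_error")
  }
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  if (!any(keep)) return(empty_hits())
  line_no <- which(keep)
  fields <- stringi::stri_split_fixed(lines[keep], "\t")
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    abort(sprintf("Malformed hit row at line %d of '%s': %d field(s), expected 12.",
                  line_no[which(nf < 12L)[1L]], path, nf[which(nf < 12L)[1L]]),
          class = "holosort_input_error")
  }
  m <- do.call(rbind, lapply(fields, `[`, seq_len(12L)))
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  qs <- num(7L); qe <- num(8L); ev <- num(11L); bs <- num(12L)
  bad <- which(is.na(qs) | is.na(qe) | is.na(ev) | is.na(bs))
  if (length(bad) > 0L) {
    abort(sprintf("Malformed hit row at line %d of '%s': non-numeric coordinate/score field.",
                  line_no[bad[1L]], path),
          class = "holosort_input_error")
  }
  tibble(
    query_id = m[, 1L],
    partner_label = partner_label,
    query_start = as.integer(pmin(qs, qe)),
    query_end = as.integer(pmax(qs, qe)),
    subject_id = m[, 2L],
    subject_start = as.integer(num(9L)),
    subject_end = as.integer(num(10L)),
    evalue = ev,
    bitscore = bs
  ) |> filter(.data$evalue <= evalue_max)
}

empty_hits <- function() {
  tibble(
    query_id = character(), partner_label = character(),
    query_start = integer(), query_end = integer(),
    subject_id = character(), subject_start = integer(),
    subject_end = integer(), evalue = numeric(), bitscore = numeric()
  )
}

#' Screen contigs for host-symbiont chimeras from alignment hits
#'
#' A contig is called a chimera when its best (highest bit score) host hit
#' and best symbiont hit describe essentially non-overlapping stretches of
#' the contig — the signature of an assembly that erroneously joined RNA
#' fragments of the two partners. Per contig: take the highest-bitscore hit
#' interval of each partner among hits spanning at least `min_hit_span`
#' bases; the verdict is `chimera` when both exist and their overlap does
#' not exceed `max_overlap_fraction` of the shorter interval, `clean` when
#' hits exist but the rule is unmet, and `no_evidence` when no qualifying
#' hit remains. Ties on bit score break deterministically (lower e-value,
#' then leftmost, then shortest interval), so the call is invariant to hit
#' row order and to duplicated rows.
#'
#' @param hits Hit tibble from [parse_hits()] (host and symbiont rows bound
#'   together), already e-value-filtered.
#' @param contig_ids Optional character vector of all screened contig ids;
#'   contigs without hits then appear as `no_evidence` rows and enter the
#'   denominator of the reported fraction.
#' @param min_hit_span Minimum interval width (bases) for a hit to anchor a
#'   call; default 50.
#' @param max_overlap_fraction Maximum tolerated overlap between the two
#'   best intervals, as a fraction of the shorter one; default 0.2.
#' @return A `chimera_screen` object; `tidy()` gives one row per contig
#'   (`contig_id`, interval columns, `overlap_bases`, `verdict`), `glance()`
#'   the summary (`n_contigs`, `n_chimera`, `fraction_chimera`).
#' @export
detect_chimeras <- function(hits, contig_ids = NULL,
                            min_hit_span = 50L, max_overlap_fraction = 0.2) {
  stopifnot(is.data.frame(hits))
  if (max_overlap_fraction < 0 || max_overlap_fraction > 1) {
    abort("`max_overlap_fraction` must be in [0, 1].",
          class = "holosort_parameter_error")
  }
  qualifying <- hits |>
    distinct() |>
    mutate(span = .data$query_end - .data$query_start + 1L) |>
    filter(.data$span >= min_hit_span)
  best <- qualifying |>
    group_by(.data$query_id, .data$partner_label) |>
    arrange(dplyr::desc(.data$bitscore), .data$evalue, .data$query_start,
            .data$span, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  wide <- best |>
    select("query_id", "partner_label",
           start = "query_start", end = "query_end") |>
    tidyr::pivot_wider(
      names_from = "partner_label",
      values_from = c("start", "end"),
      names_glue = "{partner_label}_{.value}"
    )
  for (col in c("host_start", "host_end", "symbiont_start", "symbiont_end")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_integer_
  }
  calls <- wide |>
    mutate(
      overlap_bases = pmax(
        0L,
        pmin(.data$host_end, .data$symbiont_end) -
          pmax(.data$host_start, .data$symbiont_start) + 1L
      ),
      shorter = pmin(.data$host_end - .data$host_start,
                     .data$symbiont_end - .data$symbiont_start) + 1L,
      verdict = dplyr::case_when(
        !is.na(.data$host_start) & !is.na(.data$symbiont_start) &
          .data$overlap_bases <= max_overlap_fraction * .data$shorter ~ "chimera",
        .default = "clean"
      )
    ) |>
    select(contig_id = "query_id", "host_start", "host_end",
           "symbiont_start", "symbiont_end", "overlap_bases", "verdict")
  if (!is.null(contig_ids)) {
    missing <- setdiff(contig_ids, calls$contig_id)
    calls <- bind_rows(
      calls,
      tibble(
        contig_id = missing,
        host_start = NA_integer_, host_end = NA_integer_,
        symbiont_start = NA_integer_, symbiont_end = NA_integer_,
        overlap_bases = NA_integer_, verdict = "no_evidence"
      )
    ) |> arrange(match(.data$contig_id, contig_ids))
  }
  structure(
    list(
      calls = calls,
      params = list(min_hit_span = as.integer(min_hit_span),
                    max_overlap_fraction = max_overlap_fraction)
    ),
    class = "chimera_screen"
  )
}

#' @export
print.chimera_screen <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<chimera_screen> %d contig(s): %d chimera (%.3f%%)\n",
              g$n_contigs, g$n_chimera, 100 * g$fraction_chimera))
  invisible(x)
}

#' @rdname detect_chimeras
#' @param x A `chimera_screen`.
#' @param ... Unused.
#' @export
tidy.chimera_screen <- function(x, ...) x$calls

#' @rdname detect_chimeras
#' @export
glance.chimera_screen <- function(x, ...) {
  n <- nrow(x$calls)
  nc <- sum(x$calls$verdict == "chimera")
  tibble(
    n_contigs = n,
    n_chimera = nc,
    fraction_chimera = if (n > 0) nc / n else 0
  )
}

#' Alignment-free per-position origin profile of a contig
#'
#' Labels every position of a contig by which partner's index covers it
#' (span coverage, as in the read classifier): `host`, `symbiont`, `both`
#' or `neither`. The summary reports the longest host-labelled and
#' symbiont-labelled runs, whether both exceed `min_run`, and the switch
#' points — boundaries where the profile transitions between host and
#' symbiont segments (ignoring interleaved both/neither stretches). On a
#' host-symbiont fusion of mutually divergent partners, the single switch
#' point falls within `k` bases of the true breakpoint, making this a
#' chimera check that needs no aligner.
#'
#' @param contig A single nucleotide string.
#' @param host_index,symbiont_index `bank_index` objects sharing one spec.
#' @param min_run Minimum run length (bases) for the dual-origin flag;
#'   default 50.
#' @return An `origin_profile`: `$profile` is a per-position tibble
#'   (`position` 1-based, `host`, `symbiont` logicals, `label`),
#'   `$summary` a one-row tibble (`longest_host_run`, `longest_symbiont_run`,
#'   `dual_origin`, `n_switch_points`, `switch_point` — the first boundary,
#'   `NA` when none). Contigs shorter than `k` give an all-`neither`
#'   profile. `autoplot()` draws the label track.
#' @export
kmer_origin_profile <- function(contig, host_index, symbiont_index, min_run = 50L) {
  stopifnot(inherits(host_index, "bank_index"), inherits(symbiont_index, "bank_index"))
  if (!specs_identical(host_index$spec, symbiont_index$spec)) {
    abort("Host and symbiont indexes were built under different k-mer specs.",
          class = "holosort_config_error")
  }
  seqs <- as_sequence_vector(contig)
  stopifnot(length(seqs) == 1L)
  l <- nchar(seqs)
  host_cov <- position_coverage(seqs, host_index)
  sym_cov <- position_coverage(seqs, symbiont_index)
  label <- dplyr::case_when(
    host_cov & sym_cov ~ "both",
    host_cov ~ "host",
    sym_cov ~ "symbiont",
    .default = "neither"
  )
  profile <- tibble(
    position = seq_len(l),
    host = host_cov,
    symbiont = sym_cov,
    label = factor(label, levels = c("host", "symbiont", "both", "neither"))
  )
  r <- rle(label)
  longest_run <- function(lab) {
    runs <- r$lengths[r$values == lab]
    if (length(runs) == 0L) 0L else max(runs)
  }
  # switch points: transitions between consecutive host/symbiont segments
  seg <- r$values[r$values %in% c("host", "symbiont")]
  seg_end <- cumsum(r$lengths)
  partner_idx <- which(r$values %in% c("host", "symbiont"))
  switches <- integer()
  if (length(partner_idx) >= 2L) {
    flips <- which(seg[-1L] != seg[-length(seg)])
    switches <- seg_end[partner_idx[flips]]
  }
  lh <- longest_run("host")
  ls <- longest_run("symbiont")
  structure(
    list(
      profile = profile,
      summary = tibble(
        length = l,
        longest_host_run = lh,
        longest_symbiont_run = ls,
        dual_origin = lh >= min_run & ls >= min_run,
        n_switch_points = length(switches),
        switch_point = if (length(switches) > 0L) switches[1L] else NA_integer_
      ),
      switch_points = switches
    ),
    class = "origin_profile"
  )
}

# Per-position span coverage (logical vector of length nchar(seq)).
position_coverage <- function(seq, index) {
  k <- index$spec$k
  l <- nchar(seq)
  if (l < k) return(rep(FALSE, l))
  w <- window_kmers(seq, index$spec)
  member <- contains_core(index, w$kmer)
  hits <- w$start[member]
  opens <- tabulate(hits + 1L, nbins = l)
  closes <- tabulate(hits + k + 1L, nbins = l + 1L)[seq_len(l)]
  cumsum(opens - closes) > 0L
}

#' @export
print.origin_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<origin_profile> %d bp: longest host run %d, longest symbiont run %d, %d switch point(s)%s\n",
    s$length, s$longest_host_run, s$longest_symbiont_run, s$n_switch_points,
    if (s$dual_origin) " [dual origin]" else ""
  ))
  invisible(x)
}

#' @rdname kmer_origin_profile
#' @param x An `origin_profile`.
#' @param ... Unused.
#' @export
tidy.origin_profile <- function(x, ...) x$profile

#' @rdname kmer_origin_profile
#' @export
glance.origin_profile <- function(x, ...) x$summary
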