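# Run `code` under a derived deterministic seed, restoring the caller's RNG
# state afterwards so generator calls never perturb user randomness.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")

#' Configuration of the synthetic holobiont generator
#'
#' Bundles every knob of the truth-labelled fixture generator. The defaults
#' describe a small but structurally faithful holobiont: two partner
#' transcript sets in which a fraction of transcripts is strictly conserved
#' (identical between partners — the origin of shared reads), a fraction
#' are homologs diverged by per-base substitutions, and the remainder are
#' partner-unique; reads of fixed length drawn uniformly along transcripts
#' with a uniform substitution error rate; and reference banks that may be
#' deliberately incomplete to emulate poorly characterised lineages.
#'
#' @param seed Integer master seed; identical config implies byte-identical
#'   outputs.
#' @param n_host_transcripts,n_symbiont_transcripts Transcript counts.
#' @param length_range Two-element integer range of transcript lengths.
#' @param divergence Per-base substitution fraction between homologous
#'   partner transcripts, in `[0, 1]`.
#' @param conserved_fraction Fraction of symbiont transcripts that are
#'   exact copies of host transcripts.
#' @param homolog_fraction Fraction of symbiont transcripts that are
#'   diverged homologs of host transcripts (the rest are unique).
#' @param bank_completeness Fraction of each partner's transcripts present
#'   in its reference bank.
#' @param read_length Read length in bases (must not exceed the shortest
#'   transcript).
#' @param error_rate Per-base substitution probability in reads.
#' @param coverage Mean sequencing depth per transcript position.
#' @param rc_prob Probability a read is emitted as its reverse complement.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_host_transcripts = 30L,
                              n_symbiont_transcripts = 30L,
                              length_range = c(500L, 1500L),
                              divergence = 0.15,
                              conserved_fraction = 0.1,
                              homolog_fraction = 0.3,
                              bank_completeness = 1,
                              read_length = 100L,
                              error_rate = 0.005,
                              coverage = 5,
                              rc_prob = 0.5) {
  fracs <- c(divergence, conserved_fraction, homolog_fraction,
             bank_completeness, error_rate, rc_prob)
  if (any(fracs < 0 | fracs > 1)) {
    abort("All fractions/probabilities must lie in [0, 1].",
          class = "holosort_parameter_error")
  }
  if (conserved_fraction + homolog_fraction > 1) {
    abort("`conserved_fraction + homolog_fraction` must not exceed 1.",
          class = "holosort_parameter_error")
  }
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2],
            read_length >= 1L, coverage >= 0)
  structure(
    list(
      seed = as.integer(seed),
      n_host_transcripts = as.integer(n_host_transcripts),
      n_symbiont_transcripts = as.integer(n_symbiont_transcripts),
      length_range = as.integer(length_range),
      divergence = divergence,
      conserved_fraction = conserved_fraction,
      homolog_fraction = homolog_fraction,
      bank_completeness = bank_completeness,
      read_length = as.integer(read_length),
      error_rate = error_rate,
      coverage = coverage,
      rc_prob = rc_prob
    ),
    class = "simulation_config"
  )
}

random_transcripts <- function(n, length_range, prefix) {
  if (n == 0L) return(tibble(id = character(), sequence = character()))
  pool <- seq.int(length_range[1L], length_range[2L])
  lens <- pool[sample.int(length(pool), n, replace = TRUE)]  # safe for scalar pool
  tibble(
    id = sprintf("%s_%03d", prefix, seq_len(n)),
    sequence = vapply(
      lens,
      function(l) paste(sample(BASES, l, replace = TRUE), collapse = ""),
      character(1L)
    )
  )
}

# Substitute each base independently with probability `rate` (always to a
# different base). Substitution-only: positions are conserved, so truth
# coverage stays exactly computable.
substitute_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    chars[hit] <- vapply(
      chars[hit],
      function(b) sample(setdiff(BASES, b), 1L),
      character(1L), USE.NAMES = FALSE
    )
  }
  paste(chars, collapse = "")
}

#' Simulate two partner transcript sets with known homology structure
#'
#' The host set is random uniform-composition sequence. The symbiont set is
#' assembled from three truth classes: `conserved` transcripts (identical
#' copies of host transcripts), `homolog` transcripts (host transcripts
#' mutated at the configured divergence rate), and `unique` transcripts
#' (freshly random, sharing no ancestry with the host). Host transcripts
#' that donated a conserved or homolog copy carry the matching class label;
#' the truth map records every pairing.
#'
#' @param config A [simulation_config()].
#' @return A list with `host` and `symbiont` transcript tibbles (`id`,
#'   `sequence`, `origin`, `class`) and `pairs`, a tibble of
#'   (`host_id`, `symbiont_id`, `class`) rows for conserved/homolog pairs.
#' @export
simulate_partners <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  local_seed(config$seed, {
    host <- random_transcripts(config$n_host_transcripts, config$length_range, "host")
    n_sym <- config$n_symbiont_transcripts
    n_cons <- round(config$conserved_fraction * n_sym)
    n_hom <- round(config$homolog_fraction * n_sym)
    if (n_cons + n_hom > nrow(host)) {
      abort("Not enough host transcripts to donate conserved + homolog copies.",
            class = "holosort_parameter_error")
    }
    n_uniq <- n_sym - n_cons - n_hom
    donors <- if (n_cons + n_hom > 0L) {
      sample(seq_len(nrow(host)), n_cons + n_hom)
    } else integer()
    cons_idx <- head(donors, n_cons)
    hom_idx <- tail(donors, n_hom)

    sym_cons <- tibble(
      id = sprintf("symbiont_cons_%03d", seq_len(n_cons)),
      sequence = host$sequence[cons_idx], class = rep("conserved", n_cons)
    )
    sym_hom <- tibble(
      id = sprintf("symbiont_hom_%03d", seq_len(n_hom)),
      sequence = vapply(host$sequence[hom_idx], substitute_bases,
                        character(1L), rate = config$divergence,
                        USE.NAMES = FALSE),
      class = rep("homolog", n_hom)
    )
    sym_uniq <- random_transcripts(n_uniq, config$length_range, "symbiont_uniq") |>
      mutate(class = "unique")

    host$class <- "unique"
    host$class[cons_idx] <- "conserved"
    host$class[hom_idx] <- "homolog"

    list(
      host = host |> mutate(origin = "host", .after = "sequence"),
      symbiont = bind_rows(sym_cons, sym_hom, sym_uniq) |>
        mutate(origin = "symbiont", .after = "sequence"),
      pairs = tibble(
        host_id = host$id[c(cons_idx, hom_idx)],
        symbiont_id = c(sym_cons$id, sym_hom$id),
        class = c(rep("conserved", n_cons), rep("homolog", n_hom))
      )
    )
  })
}

#' Simulate truth-labelled reads from a transcript set
#'
#' Reads of fixed length start uniformly along each transcript, at a depth
#' of `coverage` reads per position on average, carry independent per-base
#' substitution errors at `error_rate`, and are emitted as the reverse
#' complement with probability `rc_prob`. The truth origin of a read is
#' `conserved` when its source transcript is identical between partners
#' (such reads should end up `shared`), otherwise the partner the
#' transcript belongs to.
#'
#' @param transcripts Transcript tibble with `id`, `sequence`, `origin`,
#'   `class` columns (from [simulate_partners()], host and/or symbiont rows
#'   bound together).
#' @param config A [simulation_config()] (`read_length` must not exceed the
#'   shortest transcript).
#' @param seed Seed for this step; defaults to `config$seed + 1`.
#' @return A tibble of labelled reads: `read_id`, `sequence`, `quality`
#'   (`NA`), `truth_origin`, `source_transcript_id`, `source_position`
#'   (1-based start on the transcript's forward strand), `source_class`,
#'   `strand`.
#' @export
simulate_reads <- function(transcripts, config = simulation_config(),
                           seed = config$seed + 1L) {
  stopifnot(inherits(config, "simulation_config"),
            is.data.frame(transcripts))
  if (nrow(transcripts) == 0L) {
    return(tibble(
      read_id = character(), sequence = character(), quality = character(),
      truth_origin = character(), source_transcript_id = character(),
      source_position = integer(), source_class = character(),
      strand = character()
    ))
  }
  rl <- config$read_length
  if (rl > min(nchar(transcripts$sequence))) {
    abort("`read_length` exceeds the shortest transcript.",
          class = "holosort_parameter_error")
  }
  local_seed(seed, {
    per_tx <- lapply(seq_len(nrow(transcripts)), function(i) {
      tx <- transcripts$sequence[i]
      l <- nchar(tx)
      n_reads <- max(1L, round(config$coverage * l / rl))
      starts <- sample.int(l - rl + 1L, n_reads, replace = TRUE)
      raw <- substring(tx, starts, starts + rl - 1L)
      with_err <- vapply(raw, substitute_bases, character(1L),
                         rate = config$error_rate, USE.NAMES = FALSE)
      rc <- runif(n_reads) < config$rc_prob
      tibble(
        sequence = ifelse(rc, revcomp(with_err), with_err),
        truth_origin = if (transcripts$class[i] == "conserved") "conserved"
                       else transcripts$origin[i],
        source_transcript_id = transcripts$id[i],
        source_position = starts,
        source_class = transcripts$class[i],
        strand = ifelse(rc, "-", "+")
      )
    })
    out <- bind_rows(per_tx)
    out |>
      mutate(
        read_id = sprintf("read_%06d", dplyr::row_number()),
        quality = NA_character_,
        .before = 1L
      ) |>
      select("read_id", "sequence", "quality", dplyr::everything())
  })
}

#' Reduce a transcript set to an incomplete reference bank
#'
#' Emulates a reference library that covers only part of a partner's
#' transcriptome — the situation that drives reads into the unassigned
#' category and that iterative enrichment is designed to mitigate. Two
#' incompleteness models:
#'
#' * `"subset"` (default): keep a uniformly sampled fraction of whole
#'   transcripts — the missing-lineage scenario; reads of dropped
#'   transcripts share nothing with the bank. Because the sample is drawn
#'   sequentially, banks built at increasing completeness under the same
#'   seed are nested.
#' * `"truncate"`: keep the 5' `bank_completeness` fraction of *every*
#'   transcript — the partial-EST scenario. Reads straddling the truncation
#'   boundary still reach the similarity threshold, which is what lets
#'   iterative enrichment walk into the unindexed remainder.
#'
#' @param transcripts Transcript tibble (`id`, `sequence`, ...).
#' @param bank_completeness Fraction kept, in `[0, 1]`.
#' @param seed Integer seed for the subsample (subset mode).
#' @param mode `"subset"` or `"truncate"`.
#' @return The reduced tibble (possibly zero rows).
#' @export
make_banks <- function(transcripts, bank_completeness = 1, seed = 1L,
                       mode = c("subset", "truncate")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(transcripts),
            bank_completeness >= 0, bank_completeness <= 1)
  if (mode == "truncate") {
    out <- transcripts |>
      mutate(sequence = substr(.data$sequence, 1L,
                               floor(bank_completeness * nchar(.data$sequence))))
    return(out |> filter(nchar(.data$sequence) > 0L))
  }
  n_keep <- round(bank_completeness * nrow(transcripts))
  if (n_keep == nrow(transcripts)) return(transcripts)
  local_seed(seed, {
    transcripts |> slice(sort(sample(dplyr::n(), n_keep)))
  })
}

#' Construct host-symbiont fusion contigs with known breakpoints
#'
#' Emulates chimeric misassemblies: each fusion contig is a host transcript
#' prefix joined to a symbiont transcript suffix, with the breakpoint drawn
#' uniformly from the middle 60% of the contig. An equal number of pure
#' (single-origin) contigs is emitted as negatives, split evenly between
#' the partners.
#'
#' @param host_tx,symbiont_tx Transcript tibbles (`id`, `sequence`).
#' @param n Number of fusion contigs (and of pure negatives).
#' @param seed Integer seed.
#' @return A list: `contigs` tibble (`id`, `sequence`, `type`) and `truth`
#'   tibble (`contig_id`, `type`, `breakpoint` — last host base of a
#'   fusion, `NA` for pure contigs — `host_id`, `symbiont_id`, `length`).
#' @export
make_fusion_contigs <- function(host_tx, symbiont_tx, n = 50L, seed = 1L) {
  stopifnot(is.data.frame(host_tx), is.data.frame(symbiont_tx))
  if (n == 0L) {
    return(list(
      contigs = tibble(id = character(), sequence = character(), type = character()),
      truth = tibble(
        contig_id = character(), type = character(), breakpoint = integer(),
        host_id = character(), symbiont_id = character(), length = integer()
      )
    ))
  }
  local_seed(seed, {
    hi <- sample(nrow(host_tx), n, replace = TRUE)
    si <- sample(nrow(symbiont_tx), n, replace = TRUE)
    fusion <- purrr::map_dfr(seq_len(n), function(j) {
      h <- host_tx$sequence[hi[j]]
      s <- symbiont_tx$sequence[si[j]]
      l <- min(nchar(h), nchar(s))
      brange <- seq.int(ceiling(0.2 * l), floor(0.8 * l))
      b <- brange[sample.int(length(brange), 1L)]
      tibble(
        id = sprintf("fusion_%03d", j),
        sequence = paste0(substr(h, 1L, b), substr(s, b + 1L, l)),
        type = "fusion",
        breakpoint = b,
        host_id = host_tx$id[hi[j]],
        symbiont_id = symbiont_tx$id[si[j]],
        length = l
      )
    })
    n_ph <- ceiling(n / 2)
    n_ps <- n - n_ph
    pure <- bind_rows(
      host_tx |> slice(sample(dplyr::n(), n_ph, replace = TRUE)) |>
        mutate(type = "pure_host", host_id = .data$id, symbiont_id = NA_character_),
      symbiont_tx |> slice(sample(dplyr::n(), n_ps, replace = TRUE)) |>
        mutate(type = "pure_symbiont", host_id = NA_character_, symbiont_id = .data$id)
    ) |>
      mutate(
        id = sprintf("pure_%03d", dplyr::row_number()),
        breakpoint = NA_integer_,
        length = nchar(.data$sequence)
      ) |>
      select("id", "sequence", "type", "breakpoint", "host_id", "symbiont_id", "length")
    all <- bind_rows(fusion, pure)
    list(
      contigs = all |> select("id", "sequence", "type"),
      truth = all |>
        select(contig_id = "id", "type", "breakpoint",
               "host_id", "symbiont_id", "length")
    )
  })
}

#' Exact alignment hits implied by fusion-contig truth
#'
#' Turns a [make_fusion_contigs()] truth table into the hit tibble an ideal
#' translated search would report: for a fusion, a host hit over the prefix
#' `[1, breakpoint]` and a symbiont hit over the suffix; for a pure contig,
#' one full-length hit against its own partner. Useful for exercising
#' [detect_chimeras()] with known ground truth and no aligner.
#'
#' @param truth Truth tibble from [make_fusion_contigs()].
#' @return A hit tibble in the [parse_hits()] schema.
#' @export
make_truth_hits <- function(truth) {
  stopifnot(is.data.frame(truth))
  rows <- purrr::map_dfr(seq_len(nrow(truth)), function(j) {
    t <- truth[j, ]
    ival <- function(label, from, to) tibble(
      query_id = t$contig_id, partner_label = label,
      query_start = as.integer(from), query_end = as.integer(to),
      subject_id = paste0(label, "_ref"),
      subject_start = 1L, subject_end = as.integer(to - from + 1L),
      evalue = 1e-20, bitscore = 2 * (to - from + 1L)
    )
    switch(t$type,
      fusion = bind_rows(
        ival("host", 1L, t$breakpoint),
        ival("symbiont", t$breakpoint + 1L, t$length)
      ),
      pure_host = ival("host", 1L, t$length),
      pure_symbiont = ival("symbiont", 1L, t$length)
    )
  })
  rows
}

#' Score a partition against simulation truth
#'
#' Joins per-read assignments with the generator's truth labels and
#' computes the confusion matrix plus per-category precision and recall.
#' The expected category of a read is its truth origin for partner-origin
#' reads, and `shared` for conserved-origin reads (a conserved read
#' genuinely belongs to both libraries, so `shared` is the correct call).
#'
#' @param assignments Per-read tibble from [classify_reads()] /
#'   `partition$assignments` (needs `read_id`, `category`).
#' @param truth Labelled-read tibble from [simulate_reads()].
#' @return A `partition_evaluation`: `$confusion` (rows = truth origin,
#'   columns = assigned category, counts), `$per_class` (expected category,
#'   precision, recall, n), `$accuracy`. `tidy()` returns the confusion
#'   matrix in long form; `glance()` a one-row summary.
#' @export
evaluate_partition <- function(assignments, truth) {
  stopifnot(is.data.frame(assignments), is.data.frame(truth))
  joined <- truth |>
    select("read_id", "truth_origin", "source_class") |>
    left_join(
      assignments |> select("read_id", "category"),
      by = "read_id"
    )
  if (any(is.na(joined$category))) {
    abort("Some truth reads are missing from the assignments.",
          class = "holosort_input_error")
  }
  confusion <- joined |>
    count(.data$truth_origin, .data$category) |>
    tidyr::complete(
      truth_origin = unique(joined$truth_origin),
      category = factor(category_levels, levels = category_levels),
      fill = list(n = 0L)
    )
  expected <- c(host = "host", symbiont = "symbiont", conserved = "shared")
  joined <- joined |> mutate(expected = expected[.data$truth_origin])
  per_class <- joined |>
    group_by(expected = .data$expected) |>
    summarise(
      n = n(),
      recall = mean(.data$category == .data$expected),
      .groups = "drop"
    ) |>
    left_join(
      joined |>
        group_by(category = .data$category) |>
        summarise(precision = mean(.data$category == .data$expected),
                  .groups = "drop") |>
        mutate(category = as.character(.data$category)),
      by = c(expected = "category")
    )
  structure(
    list(
      confusion = confusion,
      per_class = per_class,
      accuracy = mean(joined$category == joined$expected),
      n_reads = nrow(joined)
    ),
    class = "partition_evaluation"
  )
}

#' @export
print.partition_evaluation <- function(x, ...) {
  cat(sprintf("<partition_evaluation> %d reads, accuracy %.4f\n",
              x$n_reads, x$accuracy))
  print(as.data.frame(
    tidyr::pivot_wider(x$confusion, names_from = "category", values_from = "n")
  ), row.names = FALSE)
  invisible(x)
}

#' @rdname evaluate_partition
#' @param x A `partition_evaluation`.
#' @param ... Unused.
#' @export
tidy.partition_evaluation <- function(x, ...) x$confusion

#' @rdname evaluate_partition
#' @export
glance.partition_evaluation <- function(x, ...) {
  tibble(n_reads = x$n_reads, accuracy = x$accuracy)
}

#' Generate a complete synthetic holobiont study
#'
#' Convenience wrapper running the whole generator: partner transcript
#' sets, labelled reads from both partners, and (possibly incomplete)
#' reference banks. This is the fixture every validation in the package is
#' run against.
#'
#' @param config A [simulation_config()].
#' @param host_completeness,symbiont_completeness Per-bank completeness
#'   overrides (default: `config$bank_completeness` for both).
#' @return A list: `partners` (see [simulate_partners()]), `reads`
#'   (labelled read tibble), `host_bank`, `symbiont_bank` (transcript
#'   tibbles), and `config`.
#' @export
simulate_holobiont <- function(config = simulation_config(),
                               host_completeness = config$bank_completeness,
                               symbiont_completeness = config$bank_completeness) {
  partners <- simulate_partners(config)
  reads <- simulate_reads(
    bind_rows(partners$host, partners$symbiont),
    config
  )
  list(
    partners = partners,
    reads = reads,
    host_bank = make_banks(partners$host, host_completeness,
                           seed = config$seed + 2L),
    symbiont_bank = make_banks(partners$symbiont, symbiont_completeness,
                               seed = config$seed + 3L),
    config = config
  )
}
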