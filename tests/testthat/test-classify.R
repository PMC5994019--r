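spec25 <- kmer_spec(k = 25, canonical = TRUE)

test_that("span coverage unions the footprints of matching k-mers", {
  # read of length 10, k = 3; bank indexes exactly the windows at starts 0 and 5
  read <- "ACGTTTGCAA"
  spec3 <- kmer_spec(k = 3, canonical = FALSE)
  bank_kmers <- c(substr(read, 1, 3), substr(read, 6, 8))  # "ACG", "TGC"... see below
  # choose the two windows explicitly: starts 0 and 5 (0-based)
  bank_kmers <- c(substr(read, 1, 3), substr(read, 6, 8))
  idx <- build_index(
    solid_filter(tibble::tibble(kmer = sort(unique(bank_kmers)), count = 1L), 1, spec3),
    "exact"
  )
  # verify the premise: only windows 0 and 5 match
  wins <- extract_kmers(read, spec3)
  expect_equal(wins$start[contains(idx, wins$kmer)], c(0L, 5L))
  cov <- coverage_similarity(read, idx)
  expect_equal(cov$covered, 6L)  # positions {0,1,2} U {5,6,7}
  expect_equal(cov$fraction, 0.6)
  # start mode counts matching window starts instead
  cov_start <- coverage_similarity(read, idx, coverage_mode = "start",
                                   denominator = "window_count")
  expect_equal(cov_start$covered, 2L)
  expect_equal(cov_start$fraction, 2 / 8)
})

test_that("self-identical reads reach full span coverage; disjoint reads none", {
  set.seed(61)
  tx <- random_seq(400)
  idx <- index_bank(tx, spec25, bank_type = "assembled")
  cov <- coverage_similarity(substr(tx, 50, 149), idx)
  expect_equal(cov$fraction, 1.0)
  stranger <- random_seq(100)
  cov0 <- coverage_similarity(stranger, idx)
  expect_equal(cov0$covered, oracle_span_coverage(stranger, idx$kmers, 25))
})

test_that("reads shorter than k are flagged too_short with zero coverage, no error", {
  idx <- index_bank(random_seq(200), spec25, bank_type = "assembled")
  cov <- coverage_similarity("ACGTACGT", idx)
  expect_true(cov$too_short)
  expect_equal(cov$covered, 0L)
  expect_equal(cov$fraction, 0)
})

test_that("span and start coverage match the brute-force oracle on random reads", {
  set.seed(71)
  bank <- vapply(1:5, function(i) random_seq(500), character(1))
  idx <- index_bank(bank, spec25, bank_type = "assembled")
  # mix of bank-derived, mutated and foreign reads
  reads <- c(
    substring(bank[1], sample(1:400, 30, TRUE), sample(1:400, 30, TRUE) + 99),
    vapply(1:30, function(i) random_seq(100), character(1))
  )
  reads <- reads[nchar(reads) == 100]
  for (r in reads) {
    expect_equal(coverage_similarity(r, idx)$covered,
                 oracle_span_coverage(r, idx$kmers, 25))
    expect_equal(
      coverage_similarity(r, idx, coverage_mode = "start")$covered,
      oracle_start_coverage(r, idx$kmers, 25)
    )
  }
})

test_that("the similarity boundary is inclusive: exactly l*s covered positions qualify", {
  # l = 50, k = 25, exactly one indexed window at the read start:
  # span coverage 25/50 = 0.5 and the read is host at s = 50
  set.seed(83)
  repeat {
    read <- random_seq(50)
    km <- canonicalize(substr(read, 1, 25))
    idx <- build_index(
      solid_filter(tibble::tibble(kmer = km, count = 1L), 1, spec25), "exact"
    )
    wins <- extract_kmers(read, spec25)
    if (sum(contains(idx, wins$kmer)) == 1L && wins$start[contains(idx, wins$kmer)] == 0L) break
  }
  empty_idx <- build_index(
    solid_filter(tibble::tibble(kmer = character(), count = integer()), 1, spec25),
    "exact"
  )
  cl <- classify_reads(read, idx, empty_idx, s_percent = 50)
  expect_equal(cl$fraction_host, 0.5)
  expect_equal(as.character(cl$category), "host")
  # just above the attained fraction the read drops out
  cl51 <- classify_reads(read, idx, empty_idx, s_percent = 51)
  expect_equal(as.character(cl51$category), "unassigned")
})

test_that("classification routes each fraction pattern to its category", {
  banks <- make_disjoint_banks()
  hidx <- index_bank(banks$host, spec25, bank_type = "assembled", source_label = "host")
  sidx <- index_bank(banks$symbiont, spec25, bank_type = "assembled", source_label = "symbiont")
  shared_bank_h <- index_bank(c(banks$host, banks$symbiont[1]), spec25, bank_type = "assembled")
  reads <- tibble::tibble(
    read_id = c("h", "s", "none"),
    sequence = c(substr(banks$host[1], 1, 100),
                 substr(banks$symbiont[1], 1, 100),
                 random_seq(100))
  )
  cl <- classify_reads(reads, hidx, sidx)
  expect_equal(as.character(cl$category), c("host", "symbiont", "unassigned"))
  # a read present in both banks is shared
  cl2 <- classify_reads(reads[2, ], shared_bank_h, sidx)
  expect_equal(as.character(cl2$category), "shared")
  # mismatched index specs are a configuration error
  sidx21 <- index_bank(banks$symbiont, kmer_spec(k = 21), bank_type = "assembled")
  expect_error(classify_reads(reads, hidx, sidx21), class = "holosort_config_error")
})

test_that("partition is disjoint, exhaustive, and its counts sum to the total", {
  cfg <- simulation_config(seed = 19, n_host_transcripts = 10,
                           n_symbiont_transcripts = 10, coverage = 2)
  sim <- simulate_holobiont(cfg)
  hidx <- index_bank(sim$host_bank, spec25, bank_type = "assembled")
  sidx <- index_bank(sim$symbiont_bank, spec25, bank_type = "assembled")
  outdir <- withr::local_tempdir()
  part <- partition_reads(sim$reads, hidx, sidx, outdir = outdir, format = "fasta")
  expect_equal(sum(part$report$n_reads), nrow(sim$reads))
  expect_equal(sum(part$report$percent), 100, tolerance = 1e-9)
  # category files partition the read set exactly
  written <- lapply(part$files, read_sequences)
  ids <- unlist(lapply(written, function(x) x$read_id))
  expect_setequal(ids, sim$reads$read_id)
  expect_equal(length(ids), length(unique(ids)))
  expect_equal(unname(vapply(written, nrow, integer(1))), part$report$n_reads)
  # empty input: all counts zero, no error
  empty <- partition_reads(sim$reads[0, ], hidx, sidx)
  expect_equal(sum(empty$report$n_reads), 0L)
})

test_that("raising s shrinks the similar sets and grows the unassigned set", {
  cfg <- simulation_config(seed = 29, n_host_transcripts = 8,
                           n_symbiont_transcripts = 8, coverage = 2,
                           error_rate = 0.02)
  sim <- simulate_holobiont(cfg)
  hidx <- index_bank(sim$host_bank, spec25, bank_type = "assembled")
  sidx <- index_bank(sim$symbiont_bank, spec25, bank_type = "assembled")
  prev_host <- NULL
  prev_sym <- NULL
  prev_unassigned <- -1L
  for (s in seq(10, 90, by = 10)) {
    cl <- classify_reads(sim$reads, hidx, sidx, s_percent = s)
    sim_host <- cl$read_id[cl$fraction_host >= s / 100 & !cl$too_short]
    sim_sym <- cl$read_id[cl$fraction_symbiont >= s / 100 & !cl$too_short]
    if (!is.null(prev_host)) {
      expect_true(all(sim_host %in% prev_host))
      expect_true(all(sim_sym %in% prev_sym))
    }
    unassigned <- sum(cl$category == "unassigned")
    expect_gte(unassigned, prev_unassigned)
    prev_host <- sim_host
    prev_sym <- sim_sym
    prev_unassigned <- unassigned
  }
})

test_that("the similarity measure is asymmetric in query and bank roles", {
  # bank B holds one long transcript; query S repeats one B k-mer amid foreign
  # sequence. Coverage of S by B's k-mers is small, coverage of the transcript
  # by S's k-mers (roles swapped) differs.
  set.seed(97)
  tx <- random_seq(300)
  piece <- substr(tx, 1, 25)
  s_query <- paste0(piece, random_seq(75))
  idx_b <- index_bank(tx, spec25, bank_type = "assembled")
  idx_s <- index_bank(s_query, spec25, bank_type = "assembled")
  f_sq <- coverage_similarity(s_query, idx_b)$fraction
  f_bq <- coverage_similarity(tx, idx_s)$fraction
  expect_equal(f_sq, 0.25)
  expect_false(isTRUE(all.equal(f_sq, f_bq)))
})

test_that("classification is deterministic for identical inputs and config", {
  cfg <- simulation_config(seed = 37, n_host_transcripts = 6,
                           n_symbiont_transcripts = 6, coverage = 1)
  sim <- simulate_holobiont(cfg)
  hidx <- index_bank(sim$host_bank, spec25, bank_type = "assembled")
  sidx <- index_bank(sim$symbiont_bank, spec25, bank_type = "assembled")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- partition_reads(sim$reads, hidx, sidx, outdir = d1, format = "fasta")
  p2 <- partition_reads(sim$reads, hidx, sidx, outdir = d2, format = "fasta")
  expect_identical(p1$assignments, p2$assignments)
  for (cat in names(p1$files)) {
    expect_identical(readLines(p1$files[[cat]]), readLines(p2$files[[cat]]))
  }
})

test_that("pair reconciliation follows the declared policies", {
  # independent: untouched
  r <- reconcile_pairs(c("host", "host"), c("symbiont", "unassigned"), "independent")
  expect_equal(as.character(r$mate1), c("host", "host"))
  expect_equal(as.character(r$mate2), c("symbiont", "unassigned"))
  # union: partner assignments propagate; conflicts become shared
  u <- reconcile_pairs(
    c("host", "host", "shared", "unassigned"),
    c("unassigned", "symbiont", "unassigned", "unassigned"),
    "union"
  )
  expect_equal(as.character(u$mate1), c("host", "shared", "shared", "unassigned"))
  expect_equal(as.character(u$mate1), as.character(u$mate2))
  # intersection: agreement required
  i <- reconcile_pairs(c("host", "host", "shared"),
                       c("host", "symbiont", "shared"), "intersection")
  expect_equal(as.character(i$mate1), c("host", "unassigned", "shared"))
})
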