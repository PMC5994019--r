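test_that("every generator is byte-deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 99, n_host_transcripts = 6,
                           n_symbiont_transcripts = 6, coverage = 1)
  a <- simulate_holobiont(cfg)
  b <- simulate_holobiont(cfg)
  expect_identical(a$partners, b$partners)
  expect_identical(a$reads, b$reads)
  expect_identical(a$host_bank, b$host_bank)
  f1 <- make_fusion_contigs(a$partners$host, a$partners$symbiont, 10, seed = 3)
  f2 <- make_fusion_contigs(b$partners$host, b$partners$symbiont, 10, seed = 3)
  expect_identical(f1, f2)
  # and the FASTA bytes agree
  p1 <- withr::local_tempfile(fileext = ".fasta")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_sequences(dplyr::rename(a$host_bank, read_id = id), p1)
  write_sequences(dplyr::rename(b$host_bank, read_id = id), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("partner structure follows the conserved/homolog/unique composition", {
  cfg <- simulation_config(seed = 7, n_host_transcripts = 20,
                           n_symbiont_transcripts = 20,
                           conserved_fraction = 0.2, homolog_fraction = 0.3)
  p <- simulate_partners(cfg)
  expect_equal(nrow(p$symbiont), 20L)
  expect_equal(sum(p$symbiont$class == "conserved"), 4L)
  expect_equal(sum(p$symbiont$class == "homolog"), 6L)
  expect_equal(sum(p$symbiont$class == "unique"), 10L)
  # conserved pairs are identical sequences
  cons <- p$pairs[p$pairs$class == "conserved", ]
  for (j in seq_len(nrow(cons))) {
    expect_identical(
      p$host$sequence[p$host$id == cons$host_id[j]],
      p$symbiont$sequence[p$symbiont$id == cons$symbiont_id[j]]
    )
  }
  # divergence 0 + all conserved makes the partner sets identical
  cfg_id <- simulation_config(seed = 8, n_host_transcripts = 10,
                              n_symbiont_transcripts = 10,
                              divergence = 0, conserved_fraction = 1,
                              homolog_fraction = 0)
  p_id <- simulate_partners(cfg_id)
  expect_setequal(p_id$symbiont$sequence, p_id$host$sequence[
    match(p_id$pairs$host_id, p_id$host$id)
  ])
})

test_that("homolog pairs differ at approximately the divergence rate", {
  cfg <- simulation_config(seed = 13, n_host_transcripts = 12,
                           n_symbiont_transcripts = 12,
                           length_range = c(1000L, 1000L),
                           divergence = 0.15, conserved_fraction = 0,
                           homolog_fraction = 1)
  p <- simulate_partners(cfg)
  mismatches <- vapply(seq_len(nrow(p$pairs)), function(j) {
    h <- strsplit(p$host$sequence[p$host$id == p$pairs$host_id[j]], "")[[1]]
    s <- strsplit(p$symbiont$sequence[p$symbiont$id == p$pairs$symbiont_id[j]], "")[[1]]
    sum(h != s)
  }, numeric(1))
  # each pair within 4 sigma of Binomial(1000, 0.15)
  sigma <- sqrt(1000 * 0.15 * 0.85)
  expect_true(all(abs(mismatches - 150) <= 4 * sigma))
})

test_that("error-free reads are exact substrings of their source (or its reverse complement)", {
  cfg <- simulation_config(seed = 21, n_host_transcripts = 5,
                           n_symbiont_transcripts = 5, error_rate = 0,
                           coverage = 1)
  p <- simulate_partners(cfg)
  tx <- dplyr::bind_rows(p$host, p$symbiont)
  reads <- simulate_reads(tx, cfg)
  for (j in sample(nrow(reads), 40)) {
    src <- tx$sequence[tx$id == reads$source_transcript_id[j]]
    sub <- substr(src, reads$source_position[j],
                  reads$source_position[j] + cfg$read_length - 1L)
    expected <- if (reads$strand[j] == "-") oracle_revcomp(sub) else sub
    expect_identical(reads$sequence[j], expected)
  }
})

test_that("read substitution errors appear at the configured rate", {
  cfg <- simulation_config(seed = 31, n_host_transcripts = 10,
                           n_symbiont_transcripts = 0,
                           length_range = c(1000L, 1000L),
                           conserved_fraction = 0, homolog_fraction = 0,
                           error_rate = 0.01, coverage = 10, rc_prob = 0)
  p <- simulate_partners(cfg)
  reads <- simulate_reads(p$host, cfg)
  total_bases <- sum(nchar(reads$sequence))
  expect_gte(total_bases, 1e5)
  mism <- sum(vapply(seq_len(nrow(reads)), function(j) {
    src <- p$host$sequence[p$host$id == reads$source_transcript_id[j]]
    ref <- substr(src, reads$source_position[j],
                  reads$source_position[j] + cfg$read_length - 1L)
    sum(strsplit(reads$sequence[j], "")[[1]] != strsplit(ref, "")[[1]])
  }, numeric(1)))
  expected <- total_bases * 0.01
  sigma <- sqrt(total_bases * 0.01 * 0.99)
  expect_lte(abs(mism - expected), 4 * sigma)
})

test_that("coverage scales the read count and completeness the bank size", {
  cfg1 <- simulation_config(seed = 41, n_host_transcripts = 8,
                            n_symbiont_transcripts = 0, conserved_fraction = 0,
                            homolog_fraction = 0, coverage = 2)
  cfg2 <- simulation_config(seed = 41, n_host_transcripts = 8,
                            n_symbiont_transcripts = 0, conserved_fraction = 0,
                            homolog_fraction = 0, coverage = 4)
  p <- simulate_partners(cfg1)
  n1 <- nrow(simulate_reads(p$host, cfg1))
  n2 <- nrow(simulate_reads(p$host, cfg2))
  expect_equal(n2 / n1, 2, tolerance = 0.02)

  tx <- p$host
  expect_identical(make_banks(tx, 1), tx)
  expect_equal(nrow(make_banks(tx, 0)), 0L)
  expect_equal(nrow(make_banks(tx, 0.5)), 4L)
  # same-seed subsets are nested across completeness levels
  b25 <- make_banks(tx, 0.25, seed = 9)
  b50 <- make_banks(tx, 0.5, seed = 9)
  expect_true(all(b25$id %in% b50$id))
  # truncate mode halves every transcript instead
  tr <- make_banks(tx, 0.5, mode = "truncate")
  expect_equal(nrow(tr), nrow(tx))
  expect_equal(nchar(tr$sequence), floor(nchar(tx$sequence) / 2))
})

test_that("fusion contigs carry exact breakpoint truth and pure negatives", {
  banks <- make_disjoint_banks(seed = 401, n = 5, len = 800)
  host_tx <- tibble::tibble(id = paste0("h", 1:5), sequence = banks$host)
  sym_tx <- tibble::tibble(id = paste0("s", 1:5), sequence = banks$symbiont)
  fus <- make_fusion_contigs(host_tx, sym_tx, n = 20, seed = 2)
  expect_equal(sum(fus$truth$type == "fusion"), 20L)
  expect_equal(sum(fus$truth$type != "fusion"), 20L)
  tf <- fus$truth[fus$truth$type == "fusion", ]
  # breakpoints inside the middle 60%
  expect_true(all(tf$breakpoint >= 0.2 * tf$length - 1))
  expect_true(all(tf$breakpoint <= 0.8 * tf$length + 1))
  # prefix/suffix reconstruct the contig
  for (j in 1:5) {
    h <- host_tx$sequence[host_tx$id == tf$host_id[j]]
    s <- sym_tx$sequence[sym_tx$id == tf$symbiont_id[j]]
    expect_identical(
      fus$contigs$sequence[fus$contigs$id == tf$contig_id[j]],
      paste0(substr(h, 1, tf$breakpoint[j]),
             substr(s, tf$breakpoint[j] + 1, tf$length[j]))
    )
  }
  expect_equal(nrow(make_fusion_contigs(host_tx, sym_tx, 0)$contigs), 0L)
})

test_that("evaluate_partition scores against truth and conserves totals", {
  cfg <- simulation_config(seed = 51, n_host_transcripts = 10,
                           n_symbiont_transcripts = 10, error_rate = 0,
                           coverage = 2)
  sim <- simulate_holobiont(cfg)
  spec <- kmer_spec(k = 25)
  hidx <- index_bank(sim$host_bank, spec, bank_type = "assembled")
  sidx <- index_bank(sim$symbiont_bank, spec, bank_type = "assembled")
  cl <- classify_reads(sim$reads, hidx, sidx)
  ev <- evaluate_partition(cl, sim$reads)
  expect_equal(sum(ev$confusion$n), nrow(sim$reads))
  # perfect divergent error-free fixture: conserved reads shared, partners right
  expect_gte(ev$accuracy, 0.99)
  # random assignment scores about 1/4
  set.seed(1)
  rand <- cl |>
    dplyr::mutate(category = factor(sample(c("host", "symbiont", "shared", "unassigned"),
                                           dplyr::n(), TRUE),
                                    levels = levels(cl$category)))
  ev_rand <- evaluate_partition(rand, sim$reads)
  expect_lt(abs(ev_rand$accuracy - 0.25), 0.08)
})
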