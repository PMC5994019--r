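# Independent brute-force oracles. Everything here is written from the
# definitions alone (nested loops, per-position marking) and shares no code
# with the package internals it checks.

BASES4 <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

# reverse complement via explicit per-character lookup
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(rev(unname(comp[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(kmers) {
  vapply(kmers, function(km) {
    rc <- oracle_revcomp(km)
    if (km <= rc) km else rc
  }, character(1), USE.NAMES = FALSE)
}

# all valid k-mers of a sequence, one window at a time
oracle_extract <- function(seq, k, canonical = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out_start <- integer(0)
  out_kmer <- character(0)
  if (n >= k) {
    for (q in 1:(n - k + 1)) {
      km <- substr(seq, q, q + k - 1)
      if (grepl("^[ACGT]+$", km)) {
        out_start <- c(out_start, q - 1L)
        out_kmer <- c(out_kmer, if (canonical) oracle_canonical(km) else km)
      }
    }
  }
  data.frame(start = out_start, kmer = out_kmer)
}

# quadratic recount of k-mer abundances over a bank
oracle_count <- function(seqs, k, canonical = TRUE) {
  all <- character(0)
  for (s in seqs) all <- c(all, oracle_extract(s, k, canonical)$kmer)
  if (length(all) == 0) return(data.frame(kmer = character(0), count = integer(0)))
  tab <- sort(table(all))
  df <- data.frame(kmer = names(tab), count = as.integer(tab))
  df[order(df$kmer), ]
}

# per-position span coverage of a read against a plain k-mer set
oracle_span_coverage <- function(read, kmer_set, k, canonical = TRUE) {
  l <- nchar(read)
  if (l < k) return(0L)
  covered <- rep(FALSE, l)
  for (q in 1:(l - k + 1)) {
    km <- substr(read, q, q + k - 1)
    if (!grepl("^[ACGT]+$", km)) next
    if (canonical) km <- oracle_canonical(km)
    if (km %in% kmer_set) covered[q:(q + k - 1)] <- TRUE
  }
  sum(covered)
}

oracle_start_coverage <- function(read, kmer_set, k, canonical = TRUE) {
  l <- nchar(read)
  if (l < k) return(0L)
  hits <- 0L
  for (q in 1:(l - k + 1)) {
    km <- substr(read, q, q + k - 1)
    if (!grepl("^[ACGT]+$", km)) next
    if (canonical) km <- oracle_canonical(km)
    if (km %in% kmer_set) hits <- hits + 1L
  }
  hits
}

# N50 from the definition: largest length L present such that contigs of
# length >= L hold at least half the bases
oracle_n50 <- function(lengths) {
  if (length(lengths) == 0 || sum(lengths) == 0) return(0)
  half <- sum(lengths) / 2
  best <- 0
  for (L in unique(lengths)) {
    if (sum(lengths[lengths >= L]) >= half && L > best) best <- L
  }
  best
}

# interval overlap by explicit position enumeration
oracle_overlap <- function(a_start, a_end, b_start, b_end) {
  length(intersect(seq(a_start, a_end), seq(b_start, b_end)))
}

# tile error-free reads across a transcript at a fixed step
tile_reads <- function(tx, read_length, step = 25L, prefix = "tile") {
  starts <- unique(c(seq(1L, nchar(tx) - read_length + 1L, by = step),
                     nchar(tx) - read_length + 1L))
  tibble::tibble(
    read_id = sprintf("%s_%04d", prefix, seq_along(starts)),
    sequence = substring(tx, starts, starts + read_length - 1L)
  )
}

# small divergent two-partner fixture shared by several tests
make_disjoint_banks <- function(seed = 11, n = 6, len = 600) {
  set.seed(seed)
  list(
    host = vapply(seq_len(n), function(i) random_seq(len), character(1)),
    symbiont = vapply(seq_len(n), function(i) random_seq(len), character(1))
  )
}

# independent per-base substitution mutator for building mutated fixtures
substitute_oracle <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (runif(1) < rate) chars[i] <- sample(setdiff(BASES4, chars[i]), 1)
  }
  paste(chars, collapse = "")
}
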