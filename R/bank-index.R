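# Two independent polynomial hashes over the 2-bit base encoding, computed
# with exact integer arithmetic in doubles (all intermediates < 2^53).
# h1 drives slot placement, h2 the fingerprint; both are deterministic
# across platforms and sessions.
HASH_P1 <- 2147483647  # 2^31 - 1
HASH_P2 <- 2147483629

kmer_hashes <- function(kmers) {
  n <- length(kmers)
  if (n == 0L) return(list(h1 = numeric(), h2 = numeric(), valid = logical()))
  valid <- !stringi::stri_detect_regex(kmers, "[^ACGT]")
  digits <- chartr("ACGT", "0123", kmers)
  k <- nchar(kmers[1L])
  h1 <- numeric(n)
  h2 <- numeric(n)
  for (i in seq_len(k)) {
    d <- suppressWarnings(as.integer(substring(digits, i, i)))
    d[is.na(d)] <- 0L
    h1 <- (h1 * 4 + d + 1) %% HASH_P1
    h2 <- (h2 * 131 + d + 17) %% HASH_P2
  }
  list(h1 = h1, h2 = h2, valid = valid)
}

#' Build a queryable membership index over a solid k-mer set
#'
#' Two modes are offered, mirroring the exact and probabilistic flavours of
#' a quasi-dictionary (minimal-perfect-hash plus fingerprint table):
#'
#' * `"exact"` (default): membership is answered against the stored k-mer
#'   set itself — no false positives, no false negatives.
#' * `"fingerprint"`: each indexed k-mer is reduced to a slot (first hash,
#'   modulo the number of indexed k-mers) holding an `fingerprint_bits`-bit
#'   fingerprint (second, independent hash). A query is declared present
#'   when its fingerprint matches one stored in its slot. Indexed k-mers are
#'   always found (zero false negatives); a foreign k-mer collides with
#'   probability about `2^-fingerprint_bits` per fingerprint resident in its
#'   slot, and with load factor 1 the empirical false-positive rate is
#'   bounded by about `2 * 2^-fingerprint_bits` (verified in the test
#'   suite). No true minimal perfect hash is constructed.
#'
#' @param solid A `solid_kmer_set` from [solid_filter()].
#' @param mode `"exact"` or `"fingerprint"`.
#' @param fingerprint_bits Fingerprint width f in bits, `4 <= f <= 30`
#'   (fingerprint mode only; below 4 bits the false-positive contract is
#'   vacuous and the call errors).
#' @return A `bank_index` object.
#' @seealso [index_bank()] for the one-call pipeline from sequences,
#'   [contains()] for queries.
#' @export
build_index <- function(solid, mode = c("exact", "fingerprint"),
                        fingerprint_bits = 12L) {
  stopifnot(inherits(solid, "solid_kmer_set"))
  mode <- match.arg(mode)
  idx <- list(
    spec = solid$spec,
    solidity_threshold = solid$solidity_threshold,
    source_label = solid$source_label,
    mode = mode,
    fingerprint_bits = NA_integer_,
    n_distinct = length(solid$kmers),
    kmers = solid$kmers,
    count = solid$count
  )
  if (mode == "fingerprint") {
    fingerprint_bits <- as.integer(fingerprint_bits)
    if (is.na(fingerprint_bits) || fingerprint_bits < 4L || fingerprint_bits > 30L) {
      abort("`fingerprint_bits` must be an integer in [4, 30].",
            class = "holosort_parameter_error")
    }
    if (idx$n_distinct == 0L) {
      abort("Fingerprint mode needs a non-empty solid set.",
            class = "holosort_parameter_error")
    }
    h <- kmer_hashes(solid$kmers)
    slot <- h$h1 %% idx$n_distinct
    fp <- as.integer(h$h2 %% 2^fingerprint_bits)
    idx$fingerprint_bits <- fingerprint_bits
    idx$n_slots <- idx$n_distinct
    idx$slots <- list2env(
      lapply(split(fp, as.character(slot)), unique),
      hash = TRUE, parent = emptyenv()
    )
  }
  structure(idx, class = "bank_index")
}

#' Query k-mers against a bank index
#'
#' Vectorised membership test honouring the index mode's contract. Queries
#' are canonicalised first when the index was built canonically, so a
#' reverse-complement form of an indexed k-mer is found. K-mers containing
#' non-ACGT symbols are never members.
#'
#' @param index A `bank_index`.
#' @param kmers Character vector of query k-mers, each of length `k`.
#' @return Logical vector, one element per query.
#' @export
contains <- function(index, kmers) {
  stopifnot(inherits(index, "bank_index"))
  if (length(kmers) == 0L) return(logical())
  if (any(nchar(kmers) != index$spec$k)) {
    abort(sprintf("All query k-mers must have length k = %d.", index$spec$k),
          class = "holosort_parameter_error")
  }
  kmers <- toupper(kmers)
  valid <- !stringi::stri_detect_regex(kmers, "[^ACGT]")
  out <- logical(length(kmers))
  if (!any(valid)) return(out)
  q <- kmers[valid]
  if (index$spec$canonical) q <- canonicalize(q)
  out[valid] <- contains_core(index, q)
  out
}

# Membership over pre-canonicalised, validated queries. Internal hot path:
# the classifier calls this once over all windows of a whole read batch.
contains_core <- function(index, q) {
  if (index$mode == "exact") return(q %in% index$kmers)
  h <- kmer_hashes(q)
  slot <- as.character(h$h1 %% index$n_slots)
  fp <- as.integer(h$h2 %% 2^index$fingerprint_bits)
  resident <- mget(slot, envir = index$slots, ifnotfound = list(integer()))
  vapply(seq_along(q), function(i) fp[i] %in% resident[[i]], logical(1L))
}

#' Build a bank index straight from sequences
#'
#' One-call pipeline: count k-mers, apply the solidity filter, build the
#' index. The solidity default depends on the nature of the library:
#' `bank_type = "reads"` uses threshold 2 (error k-mers in raw short-read
#' banks are mostly singletons), `bank_type = "assembled"` uses threshold 1
#' (every k-mer of an assembled transcript, gene or EST is presumed real).
#' An explicit `solidity_threshold` overrides either default.
#'
#' @param bank Sequences (character vector, tibble with `sequence`, or
#'   `DNAStringSet`) or one or more FASTA/FASTQ paths (read via
#'   [read_sequences()]; gzip accepted).
#' @param spec A [kmer_spec()].
#' @param bank_type `"reads"` or `"assembled"`; sets the solidity default.
#' @param solidity_threshold Optional explicit threshold.
#' @param source_label Bank name carried into reports.
#' @inheritParams build_index
#' @return A `bank_index`.
#' @examples
#' idx <- index_bank(c("ACGTACGTACGT"), kmer_spec(k = 4), bank_type = "assembled")
#' contains(idx, "ACGT")
#' @export
index_bank <- function(bank, spec = kmer_spec(), bank_type = c("reads", "assembled"),
                       solidity_threshold = NULL, source_label = "bank",
                       mode = c("exact", "fingerprint"), fingerprint_bits = 12L) {
  bank_type <- match.arg(bank_type)
  if (is.character(bank) && length(bank) >= 1L && all(file.exists(bank))) {
    bank <- read_sequences(bank)
  }
  tau <- solidity_threshold %||% if (bank_type == "reads") 2L else 1L
  counts <- count_kmers(bank, spec)
  solid <- solid_filter(counts, tau, spec, source_label)
  build_index(solid, mode = match.arg(mode), fingerprint_bits = fingerprint_bits)
}

#' @export
print.bank_index <- function(x, ...) {
  extra <- if (x$mode == "fingerprint") {
    sprintf(", fingerprint %d bits", x$fingerprint_bits)
  } else ""
  cat(sprintf(
    "<bank_index> '%s': %d distinct solid k-mers (%s, solidity >= %d, %s mode%s)\n",
    x$source_label, x$n_distinct, format(x$spec), x$solidity_threshold,
    x$mode, extra
  ))
  invisible(x)
}

#' @rdname build_index
#' @param x A `bank_index`.
#' @param ... Unused.
#' @export
tidy.bank_index <- function(x, ...) {
  tibble(kmer = x$kmers, count = x$count)
}

#' @rdname build_index
#' @export
glance.bank_index <- function(x, ...) {
  tibble(
    source_label = x$source_label,
    k = x$spec$k,
    canonical = x$spec$canonical,
    solidity_threshold = x$solidity_threshold,
    mode = x$mode,
    fingerprint_bits = x$fingerprint_bits,
    n_distinct = x$n_distinct
  )
}

#' Persist and restore a bank index
#'
#' The dump is a small self-describing text format: a header of `#key value`
#' lines (format version, k, strand handling, solidity threshold, mode,
#' fingerprint width, distinct count, label) followed by one `kmer<TAB>count`
#' row per solid k-mer, sorted. [read_bank_index()] rebuilds the index in the
#' dumped mode and refuses a file whose `k` differs from `expect_k` when one
#' is given, so mismatched indexes cannot be silently combined.
#'
#' @param index A `bank_index`.
#' @param path Output/input file path.
#' @param expect_k If non-NULL, required `k` of the loaded index.
#' @return `write_bank_index()` returns `path` invisibly; `read_bank_index()`
#'   a `bank_index`.
#' @export
write_bank_index <- function(index, path) {
  stopifnot(inherits(index, "bank_index"))
  header <- c(
    "#holosort_index 1",
    sprintf("#k %d", index$spec$k),
    sprintf("#canonical %s", index$spec$canonical),
    sprintf("#solidity_threshold %d", index$solidity_threshold),
    sprintf("#mode %s", index$mode),
    sprintf("#fingerprint_bits %s", index$fingerprint_bits),
    sprintf("#distinct %d", index$n_distinct),
    sprintf("#label %s", index$source_label)
  )
  writeLines(c(header, paste(index$kmers, index$count, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_bank_index
#' @export
read_bank_index <- function(path, expect_k = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1L] != "#holosort_index 1") {
    abort(sprintf("'%s' is not a holosort index dump.", path),
          class = "holosort_io_error")
  }
  hdr_lines <- lines[startsWith(lines, "#")][-1L]
  kv <- stringi::stri_split_fixed(hdr_lines, " ", n = 2L)
  hdr <- setNames(
    vapply(kv, `[`, character(1L), 2L),
    sub("^#", "", vapply(kv, `[`, character(1L), 1L))
  )
  k <- as.integer(hdr[["k"]])
  if (!is.null(expect_k) && k != as.integer(expect_k)) {
    abort(sprintf("Index '%s' was built with k = %d, expected k = %d.",
                  path, k, as.integer(expect_k)),
          class = "holosort_config_error")
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  parts <- stringi::stri_split_fixed(body, "\t", n = 2L)
  solid <- structure(
    list(
      kmers = vapply(parts, `[`, character(1L), 1L),
      count = as.integer(vapply(parts, `[`, character(1L), 2L)),
      spec = kmer_spec(k = k, canonical = as.logical(hdr[["canonical"]])),
      solidity_threshold = as.integer(hdr[["solidity_threshold"]]),
      source_label = hdr[["label"]]
    ),
    class = "solid_kmer_set"
  )
  if (identical(hdr[["mode"]], "fingerprint")) {
    build_index(solid, "fingerprint",
                fingerprint_bits = as.integer(hdr[["fingerprint_bits"]]))
  } else {
    build_index(solid, "exact")
  }
}
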