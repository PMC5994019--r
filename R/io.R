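is_fastq_path <- function(path) {
  grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
}

#' Read sequences from FASTA/FASTQ into a tibble
#'
#' Thin tidy wrapper around Biostrings readers. The format is taken from
#' each file's extension (`.fastq`/`.fq`, optionally `.gz`, are FASTQ;
#' everything else FASTA) unless forced. Multiple paths form one bank: rows
#' are concatenated in the order given, which is how multi-file reference
#' libraries are expressed.
#'
#' @param paths One or more file paths (gzip-compressed accepted).
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return A tibble with columns `read_id`, `sequence`, and `quality`
#'   (`NA` for FASTA records).
#' @export
read_sequences <- function(paths, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(sprintf("Input file(s) not found: %s", paste(missing, collapse = ", ")),
          class = "holosort_io_error")
  }
  purrr::map_dfr(paths, function(p) {
    fq <- switch(format, auto = is_fastq_path(p), fasta = FALSE, fastq = TRUE)
    if (fq) {
      x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
      qual <- as.character(S4Vectors::mcols(x)$qualities)
    } else {
      x <- Biostrings::readDNAStringSet(p, format = "fasta")
      qual <- rep(NA_character_, length(x))
    }
    tibble(
      read_id = sub("\\s.*$", "", names(x)),
      sequence = unname(as.character(x)),
      quality = unname(qual)
    )
  })
}

#' Write a sequence tibble to FASTA or FASTQ
#'
#' @param seqs Tibble with `read_id` and `sequence` columns (and optionally
#'   `quality` for FASTQ; missing qualities are filled with a constant
#'   placeholder).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(seqs), all(c("read_id", "sequence") %in% names(seqs)))
  x <- Biostrings::DNAStringSet(as.character(seqs$sequence))
  names(x) <- as.character(seqs$read_id)
  compress <- grepl("\\.gz$", path)
  if (format == "fastq") {
    qual <- if ("quality" %in% names(seqs)) as.character(seqs$quality) else NA_character_
    qual <- ifelse(is.na(qual), strrep("I", nchar(seqs$sequence)), qual)
    Biostrings::writeXStringSet(
      x, path, format = "fastq", compress = compress,
      qualities = Biostrings::BStringSet(qual)
    )
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", compress = compress)
  }
  invisible(path)
}
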