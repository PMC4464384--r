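#' Read and write sequence files
#'
#' Thin wrappers around Biostrings that move sequences between FASTA/FASTQ
#' files and the package's read tibbles (see [seq_tbl()]). FASTA headers of
#' the form `id_cov_<float>` carry contig mean fold-coverage and are parsed
#' by [read_contigs()].
#'
#' @param path File path.
#' @return A read tibble (`read_id`, `bases`, `quality`).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  seq_tbl(names(x), as.character(x),
          as.character(S4Vectors::mcols(x)$qualities))
}

#' @rdname read_fastq
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  seq_tbl(names(x), as.character(x))
}

#' @rdname read_fastq
#' @param reads A read tibble.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  qual <- reads$quality
  if (any(is.na(qual))) abort("write_fastq requires quality strings")
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' @rdname read_fastq
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read/write contig FASTA with coverage-tagged headers
#'
#' Contig mean fold-coverage travels in the FASTA header as a `_cov_<float>`
#' suffix (e.g. `>contig7_cov_451.3`), so no read mapping is needed
#' downstream.
#'
#' @param path File path.
#' @return A contig tibble (`contig_id`, `bases`, `length`, `coverage`).
#' @export
read_contigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  hdr <- names(x)
  m <- regmatches(hdr, regexpr("_cov_[0-9.eE+-]+$", hdr))
  cov <- rep(NA_real_, length(hdr))
  has <- grepl("_cov_[0-9.eE+-]+$", hdr)
  cov[has] <- as.numeric(sub("^_cov_", "", m))
  bases <- unname(as.character(x))
  tibble(
    contig_id = sub("_cov_[0-9.eE+-]+$", "", hdr),
    bases = bases,
    length = nchar(bases),
    coverage = cov
  )
}

#' @rdname read_contigs
#' @param contigs A contig tibble with `contig_id`, `bases`, `coverage`.
#' @export
write_contigs <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$bases)
  names(x) <- sprintf("%s_cov_%g", contigs$contig_id, contigs$coverage)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read/write tab-separated tables
#'
#' @param x A data frame.
#' @param path File path.
#' @return A tibble (`read_tsv_table`) or `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
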