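#' @importFrom rlang .data %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap list_rbind
#' @importFrom stringr str_sub str_length str_count str_detect
NULL

# IUPAC nucleotide codes -> the set of bases each matches
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' Ambiguity codes are complemented according to the IUPAC table.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out[!ok] <- x[!ok]
  out
}

#' Does a sequence match an IUPAC pattern at a fixed position?
#'
#' Compares `seq_part` (plain A/C/G/T/N bases) against `pattern` (IUPAC
#' degenerate codes) of the same length and returns the number of positions
#' where the base is not in the pattern's allowed set. An N in the sequence
#' never matches a non-N pattern code.
#'
#' @param seq_part,pattern Single strings of equal length.
#' @return Integer mismatch count.
#' @keywords internal
iupac_mismatches <- function(seq_part, pattern) {
  s <- strsplit(seq_part, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (length(s) != length(p)) abort("sequence and pattern lengths differ")
  mm <- 0L
  for (i in seq_along(p)) {
    allowed <- IUPAC_SETS[[p[i]]]
    if (is.null(allowed)) abort(paste0("unknown IUPAC code: ", p[i]))
    if (!(s[i] %in% allowed)) mm <- mm + 1L
  }
  mm
}

# Phred+33 helpers ------------------------------------------------------------

#' Encode/decode Phred+33 quality strings
#'
#' @param q Integer vector of Phred scores (`phred_encode`) or a single
#'   quality string (`phred_decode`).
#' @return A quality string, or an integer vector of scores.
#' @export
phred_encode <- function(q) {
  intToUtf8(as.integer(round(q)) + 33L, multiple = FALSE)
}

#' @rdname phred_encode
#' @export
phred_decode <- function(q) {
  utf8ToInt(q) - 33L
}

#' Build a read tibble
#'
#' The package-wide representation of sequence reads: one row per read with
#' columns `read_id`, `bases` and (optionally) `quality`, a Phred+33 string of
#' the same length as `bases`.
#'
#' @param read_id Character ids.
#' @param bases Character DNA sequences.
#' @param quality Optional character Phred+33 strings (NA allowed).
#' @param ... Further columns (e.g. `sample_id`) passed to [tibble::tibble()].
#' @return A tibble with one row per read.
#' @export
seq_tbl <- function(read_id, bases, quality = NA_character_, ...) {
  out <- tibble(read_id = as.character(read_id),
                bases = toupper(as.character(bases)),
                quality = quality, ...)
  bad <- !is.na(out$quality) & nchar(out$quality) != nchar(out$bases)
  if (any(bad)) abort("quality length must equal bases length")
  out
}

# Random DNA with given GC content (order-0 Markov chain)
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Apply substitution errors at a per-base rate; returns the mutated string.
mutate_bases <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < error_rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(alt, b), 1L), "")
  }
  paste(ch, collapse = "")
}

# Draw a Phred+33 quality string: Normal(mean, sd) clipped to [2, 40].
random_quality <- function(n, mean = 35, sd = 4) {
  q <- pmin(40L, pmax(2L, as.integer(round(stats::rnorm(n, mean, sd)))))
  phred_encode(q)
}

# Weighted median used by the TNF robust centroid.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}
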