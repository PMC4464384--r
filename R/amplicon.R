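#' Demultiplex barcoded amplicon reads
#'
#' Assigns each read to the sample whose barcode is within `max_mismatch`
#' Hamming distance of the read's leading bases, and strips the barcode.
#' Reads shorter than the barcode, reads matching no barcode, and ties (two
#' barcodes at the same admissible distance) are left unassigned.
#'
#' @param reads Read tibble (see [seq_tbl()]).
#' @param barcodes Named character vector `sample_id -> barcode`; equal
#'   lengths, unique.
#' @param max_mismatch Maximum Hamming distance for an assignment.
#' @return The read tibble with a `sample_id` column (`NA` = unassigned);
#'   assigned rows have the barcode removed from `bases` (and `quality`).
#'   Assigned + unassigned rows partition the input.
#' @export
demultiplex <- function(reads, barcodes, max_mismatch = 1) {
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1) abort("barcodes must have equal length")
  if (anyDuplicated(barcodes)) abort("barcodes must be unique")

  prefix <- str_sub(reads$bases, 1, bl)
  pm <- vapply(barcodes, function(b) {
    x <- utf8ToInt(b)
    vapply(prefix, function(p) {
      if (nchar(p) < bl) return(bl + 1L)  # too short: worse than any barcode
      sum(utf8ToInt(p) != x)
    }, 1L, USE.NAMES = FALSE)
  }, integer(nrow(reads)))
  pm <- matrix(pm, nrow = nrow(reads))

  best <- apply(pm, 1, min)
  n_best <- rowSums(pm == best)
  hit <- best <= max_mismatch & n_best == 1L
  which_bc <- apply(pm, 1, which.min)

  out <- reads
  out$sample_id <- ifelse(hit, names(barcodes)[which_bc], NA_character_)
  out$bases[hit] <- str_sub(out$bases[hit], bl + 1L)
  if ("quality" %in% names(out)) {
    has_q <- hit & !is.na(out$quality)
    out$quality[has_q] <- str_sub(out$quality[has_q], bl + 1L)
  }
  out
}

#' Trim amplicon primers
#'
#' Removes the forward primer from the read start (IUPAC-degenerate codes
#' honoured, up to 1 mismatch per 10 primer bases, rounded up) and, when a
#' reverse-complemented member of the reverse-primer cocktail is found at the
#' read's 3' end, trims from that match onward. Reads without a forward
#' primer match are dropped; the drop count is attached as attribute
#' `n_dropped` and reported via a message.
#'
#' @param reads Read tibble (post-[demultiplex()], barcode already removed).
#' @param primer_fwd Forward primer (IUPAC codes allowed).
#' @param primer_rev Character vector of reverse primers (the study used a
#'   cocktail of four); all are searched. NULL to skip 3' trimming.
#' @param quiet Suppress the drop-count message.
#' @return The trimmed read tibble (kept reads only), with attribute
#'   `n_dropped`.
#' @export
trim_primers <- function(reads, primer_fwd, primer_rev = NULL, quiet = FALSE) {
  fl <- nchar(primer_fwd)
  allow_f <- ceiling(fl / 10)
  keep <- logical(nrow(reads))
  bases <- reads$bases
  quality <- if ("quality" %in% names(reads)) reads$quality else rep(NA_character_, nrow(reads))

  rev_rc <- if (!is.null(primer_rev)) revcomp(primer_rev) else character()

  for (i in seq_len(nrow(reads))) {
    b <- bases[i]
    if (nchar(b) < fl) next
    if (iupac_mismatches(substr(b, 1, fl), primer_fwd) > allow_f) next
    keep[i] <- TRUE
    b <- substr(b, fl + 1L, nchar(b))
    q <- if (!is.na(quality[i])) substr(quality[i], fl + 1L, nchar(quality[i])) else NA_character_

    # search the 3' end for any reverse primer (reverse-complemented)
    cut <- NA_integer_
    for (rp in rev_rc) {
      rl <- nchar(rp)
      allow_r <- ceiling(rl / 10)
      # scan candidate start positions from the rightmost possible, inward
      max_scan <- min(nchar(b) - rl + 1L, nchar(b))
      if (max_scan < 1L) next
      for (pos in seq(max_scan, max(1L, max_scan - 2L * rl))) {
        if (iupac_mismatches(substr(b, pos, pos + rl - 1L), rp) <= allow_r) {
          cut <- min(cut, pos, na.rm = TRUE)
          break
        }
      }
    }
    if (!is.na(cut)) {
      b <- substr(b, 1L, cut - 1L)
      if (!is.na(q)) q <- substr(q, 1L, cut - 1L)
    }
    bases[i] <- b
    quality[i] <- q
  }

  out <- reads[keep, , drop = FALSE]
  out$bases <- bases[keep]
  if ("quality" %in% names(reads)) out$quality <- quality[keep]
  n_dropped <- sum(!keep)
  if (!quiet && n_dropped > 0) {
    inform(paste0(n_dropped, " read(s) without a forward-primer match dropped"))
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Normalize sequencing depth by taking the first n reads
#'
#' Depth normalization as done in the source workflow: keep the first
#' `min(n, batch size)` reads of each sample in input order (the study used
#' n = 8,951). Optionally subsample at random instead via `shuffle_seed`.
#' The operation is idempotent and always returns a prefix of the input
#' (per sample) when `shuffle_seed` is NULL.
#'
#' @param reads Read tibble; if a `sample_id` column is present the rule is
#'   applied per sample.
#' @param n Number of reads to keep per sample (>= 1).
#' @param shuffle_seed Optional seed for random (rather than first-n)
#'   subsampling.
#' @param quiet Suppress warnings about samples smaller than `n`.
#' @return The normalized read tibble.
#' @export
normalize_depth <- function(reads, n, shuffle_seed = NULL, quiet = FALSE) {
  if (n < 1) abort("n must be >= 1")
  take <- function(df, label) {
    if (nrow(df) < n && !quiet) {
      warn(paste0("sample ", label, " has only ", nrow(df), " reads (< ", n, ")"))
    }
    if (is.null(shuffle_seed)) {
      df[seq_len(min(n, nrow(df))), , drop = FALSE]
    } else {
      withr::with_seed(shuffle_seed,
        df[sort(sample.int(nrow(df), min(n, nrow(df)))), , drop = FALSE])
    }
  }
  if ("sample_id" %in% names(reads)) {
    reads |>
      group_by(.data$sample_id) |>
      group_modify(~ take(.x, .y$sample_id)) |>
      ungroup() |>
      relocate("sample_id", .after = dplyr::last_col())
  } else {
    take(reads, "(all)")
  }
}
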