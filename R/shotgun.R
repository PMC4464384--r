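#' Quality-filter reads
#'
#' Discards a read iff its fraction of unknown bases (N) exceeds
#' `max_n_frac` OR the fraction of bases below Phred `low_q` exceeds
#' `max_lowq_frac`. Both comparisons are strict (`>`), so a 100 bp read with
#' exactly 10 N or exactly 50 bases at Q19 is kept. Relaxing either
#' threshold can only keep more reads (the rule is monotone).
#'
#' Works on single-read tibbles (`bases`/`quality`) or paired tibbles
#' (`fwd`/`fwd_quality`/`rev`/`rev_quality`; a pair is discarded if either
#' mate fails).
#'
#' @param reads Read or pair tibble.
#' @param max_n_frac Maximum tolerated N fraction (default 0.10).
#' @param low_q Phred score below which a base counts as low quality
#'   (default 20).
#' @param max_lowq_frac Maximum tolerated low-quality fraction (default 0.50).
#' @return The kept rows, with attribute `filter_report` (tibble: `n_in`,
#'   `n_kept`, `n_fail_n`, `n_fail_quality`).
#' @export
quality_filter <- function(reads, max_n_frac = 0.10, low_q = 20,
                           max_lowq_frac = 0.50) {
  fail_one <- function(bases, quality) {
    if (anyNA(quality)) abort("quality strings required for quality filtering")
    n_frac <- str_count(bases, "N") / nchar(bases)
    lowq_frac <- vapply(quality,
                        function(q) mean(phred_decode(q) < low_q),
                        1, USE.NAMES = FALSE)
    list(n = n_frac > max_n_frac, q = lowq_frac > max_lowq_frac)
  }
  if (all(c("fwd", "rev") %in% names(reads))) {
    f1 <- fail_one(reads$fwd, reads$fwd_quality)
    f2 <- fail_one(reads$rev, reads$rev_quality)
    fail_n <- f1$n | f2$n
    fail_q <- f1$q | f2$q
  } else {
    f <- fail_one(reads$bases, reads$quality)
    fail_n <- f$n
    fail_q <- f$q
  }
  keep <- !(fail_n | fail_q)
  out <- reads[keep, , drop = FALSE]
  attr(out, "filter_report") <- tibble(
    n_in = nrow(reads), n_kept = sum(keep),
    n_fail_n = sum(fail_n), n_fail_quality = sum(fail_q)
  )
  out
}

#' De-replicate reads by prefix identity
#'
#' Groups reads whose first `prefix_len` bases are identical and keeps the
#' first-encountered read of each group as the representative, preserving
#' input order (the study collapsed Illumina duplicates on identical first
#' 50 bp). For pair tibbles the forward mate's prefix is used by default;
#' `both_mates = TRUE` keys on the concatenation of both mates' prefixes.
#' The operation is idempotent and never increases the read count; cluster
#' sizes partition the input.
#'
#' @param reads Read or pair tibble.
#' @param prefix_len Prefix length in bp (default 50).
#' @param both_mates Key on both mates' prefixes (pairs only).
#' @return Representative rows in input order, with attribute `clusters`
#'   (tibble: representative id, `size`).
#' @export
dereplicate <- function(reads, prefix_len = 50, both_mates = FALSE) {
  paired <- all(c("fwd", "rev") %in% names(reads))
  key <- if (paired) {
    if (both_mates) {
      paste0(str_sub(reads$fwd, 1, prefix_len), "|",
             str_sub(reads$rev, 1, prefix_len))
    } else {
      str_sub(reads$fwd, 1, prefix_len)
    }
  } else {
    str_sub(reads$bases, 1, prefix_len)
  }
  first <- !duplicated(key)
  out <- reads[first, , drop = FALSE]
  id_col <- if (paired) "pair_id" else "read_id"
  sizes <- as.integer(table(factor(key, levels = key[first])))
  attr(out, "clusters") <- tibble(!!id_col := out[[id_col]], size = sizes)
  out
}

#' Merge read pairs into tags by 3' overlap
#'
#' Reverse-complements the reverse mate and searches all substitution-only
#' overlaps of at least `min_overlap` bases (the study required >= 10 bp)
#' between the forward read's 3' end and the reverse-complemented mate's 5'
#' end. Among overlaps with mismatch fraction <= `max_mismatch_frac`, the
#' one with the most matching bases wins; ties go to the longer overlap, and
#' a pair whose best overlaps remain tied is left unmerged as ambiguous. At
#' disagreeing overlap positions the consensus takes the higher-quality
#' base; at agreeing positions the consensus quality is the larger of the
#' two.
#'
#' @param pairs Pair tibble (`pair_id`, `fwd`, `fwd_quality`, `rev`,
#'   `rev_quality`).
#' @param min_overlap Minimum admissible overlap (bp).
#' @param max_mismatch_frac Maximum mismatch fraction inside the overlap.
#' @return A list: `tags` (tibble `pair_id`, `bases`, `quality`, `length`,
#'   `overlap`, `n_mismatch`) and `unmerged` (the input rows that failed).
#' @export
merge_tags <- function(pairs, min_overlap = 10, max_mismatch_frac = 0.10) {
  n <- nrow(pairs)
  merged <- vector("list", n)
  ok <- logical(n)
  rc_rev <- revcomp(pairs$rev)
  rc_q <- vapply(pairs$rev_quality,
                 function(q) paste(rev(strsplit(q, "", fixed = TRUE)[[1]]),
                                   collapse = ""),
                 "", USE.NAMES = FALSE)

  for (i in seq_len(n)) {
    f <- strsplit(pairs$fwd[i], "", fixed = TRUE)[[1]]
    r <- strsplit(rc_rev[i], "", fixed = TRUE)[[1]]
    fq <- phred_decode(pairs$fwd_quality[i])
    rq <- phred_decode(rc_q[i])
    lf <- length(f); lr <- length(r)
    if (min(lf, lr) < min_overlap) next

    best_o <- 0L; best_m <- -1L; tied <- FALSE
    for (o in seq.int(min_overlap, min(lf, lr))) {
      m <- sum(f[(lf - o + 1L):lf] == r[1:o])
      if ((o - m) / o > max_mismatch_frac) next
      if (m > best_m || (m == best_m && o > best_o)) {
        tied <- FALSE
        best_m <- m; best_o <- o
      } else if (m == best_m && o == best_o) {
        tied <- TRUE
      }
    }
    if (best_m < 0L || tied) next

    o <- best_o
    fo <- (lf - o + 1L):lf
    ro <- 1:o
    cons <- f[fo]
    dis <- which(f[fo] != r[ro])
    take_rev <- dis[rq[ro][dis] > fq[fo][dis]]
    cons[take_rev] <- r[ro][take_rev]
    cons_q <- pmax(fq[fo], rq[ro])

    left_b <- if (o < lf) f[seq_len(lf - o)] else character(0)
    left_q <- if (o < lf) fq[seq_len(lf - o)] else integer(0)
    right_b <- if (o < lr) r[(o + 1L):lr] else character(0)
    right_q <- if (o < lr) rq[(o + 1L):lr] else integer(0)

    tag_b <- paste(c(left_b, cons, right_b), collapse = "")
    tag_q <- phred_encode(c(left_q, cons_q, right_q))
    merged[[i]] <- tibble(pair_id = pairs$pair_id[i], bases = tag_b,
                          quality = tag_q, length = nchar(tag_b),
                          overlap = o, n_mismatch = o - best_m)
    ok[i] <- TRUE
  }
  list(
    tags = if (any(ok)) list_rbind(merged[ok]) else
      tibble(pair_id = character(), bases = character(), quality = character(),
             length = integer(), overlap = integer(), n_mismatch = integer()),
    unmerged = pairs[!ok, , drop = FALSE]
  )
}
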