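# Shared helpers for the dwbiofilm test suite.

# Random DNA string (test-local; independent of package internals).
rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Substitute the bases at `positions` with a different base each.
mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# All set partitions of 1..n as lists of integer blocks (restricted growth
# strings). Feasible for n <= 9.
all_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      out[[length(out) + 1]] <<- split(seq_len(n), rgs)
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) {
      rgs[i] <<- v
      recurse(i + 1, max(maxv, v))
    }
  }
  recurse(1, 0)
  out
}

# Does every block of `blocks` (integer indices into dm) satisfy
# max intra-block distance <= threshold?
partition_valid <- function(blocks, dm, threshold) {
  all(vapply(blocks, function(b) {
    length(b) == 1 || max(dm[b, b]) <= threshold
  }, TRUE))
}

# Rand index of two label vectors.
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# Independent canonical-TNF oracle: count 4-mers by hand, fold by
# min(kmer, revcomp) computed with chartr, normalize.
tnf_oracle <- function(seq) {
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }
  n <- nchar(seq)
  words <- substring(seq, 1:(n - 3), 4:n)
  words <- words[!grepl("[^ACGT]", words)]
  canon <- vapply(words, function(w) min(w, rc1(w)), "", USE.NAMES = FALSE)
  tab <- table(canon)
  tab / sum(tab)
}

# One deterministic pair of 100 bp mates whose true overlap is exactly `t`
# bases: fragment C^(100-t) A^t G^(100-t). Any shifted overlap o = t + s
# incurs 2s run-boundary mismatches (fraction 2s/(t+s) > 10% for t <= 19,
# s >= 1), so the true overlap is the only admissible one.
overlap_pair <- function(t) {
  frag <- paste0(strrep("C", 100 - t), strrep("A", t), strrep("G", 100 - t))
  L <- nchar(frag)
  tibble::tibble(
    pair_id = "p1",
    fwd = substr(frag, 1, 100),
    fwd_quality = strrep("I", 100),
    rev = dwbiofilm::revcomp(substr(frag, L - 99, L)),
    rev_quality = strrep("I", 100)
  )
}
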