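#' Pairwise sequence distances
#'
#' Distance between two reads is `mismatches / aligned columns`, where the
#' aligned columns come from a pairwise global alignment with free terminal
#' gaps (match +1, mismatch -1, gap -2); terminal gap columns are excluded,
#' internal gap columns count as mismatches. With `mode = "aligned"` the
#' sequences are taken as rows of an existing multiple alignment (`-` or `.`
#' for gaps) and compared column-wise under the same rule.
#'
#' @param reads Read tibble (>= 2 rows, non-empty sequences).
#' @param mode `"pairwise"` (align here) or `"aligned"` (pre-aligned input).
#' @return A symmetric distance matrix with `read_id` dimnames, values in
#'   [0, 1].
#' @export
pairwise_distance <- function(reads, mode = c("pairwise", "aligned")) {
  mode <- match.arg(mode)
  if (nrow(reads) < 2) abort("need at least 2 reads")
  if (any(!nzchar(reads$bases))) abort("empty sequence")
  ids <- reads$read_id
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))

  if (mode == "aligned") {
    if (length(unique(nchar(reads$bases))) != 1) {
      abort("aligned mode requires equal-length rows")
    }
    chars <- strsplit(toupper(reads$bases), "", fixed = TRUE)
    chars <- lapply(chars, function(x) { x[x == "."] <- "-"; x })
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- chars[[i]]; b <- chars[[j]]
        # drop columns gapped at either row's terminal runs
        core <- seq(max(first_base(a), first_base(b)),
                    min(last_base(a), last_base(b)))
        keep <- !(a[core] == "-" & b[core] == "-")
        mm <- sum(a[core][keep] != b[core][keep])
        d[i, j] <- d[j, i] <- mm / sum(keep)
      }
    }
    return(d)
  }

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  seqs <- Biostrings::DNAStringSet(reads$bases)
  for (j in 2:n) {
    aln <- Biostrings::pairwiseAlignment(
      seqs[seq_len(j - 1)], seqs[[j]], type = "overlap",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
    pa <- as.character(Biostrings::alignedPattern(aln))
    sa <- as.character(Biostrings::alignedSubject(aln))
    for (i in seq_len(j - 1)) {
      a <- strsplit(pa[i], "", fixed = TRUE)[[1]]
      b <- strsplit(sa[i], "", fixed = TRUE)[[1]]
      d[i, j] <- d[j, i] <- sum(a != b) / length(a)
    }
  }
  d
}

first_base <- function(x) which(x != "-")[1]
last_base <- function(x) utils::tail(which(x != "-"), 1)

#' Complete-linkage OTU clustering at a distance threshold
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise read distance. Starting from singletons, the pair of
#' clusters with the smallest complete-linkage distance is merged until no
#' merge stays at or below `threshold`; ties are broken by the
#' lexicographically smallest pair of cluster representative ids. Every OTU
#' therefore satisfies max intra-OTU distance <= threshold, and the result
#' is deterministic.
#'
#' @param dm Distance matrix from [pairwise_distance()].
#' @param threshold Clustering distance in [0, 1]; the study used 0.03 and
#'   0.06.
#' @return Tibble `read_id`, `otu_id`, with attribute `threshold`.
#' @export
cluster_complete_linkage <- function(dm, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  ids <- rownames(dm)
  clusters <- as.list(ids)

  repeat {
    k <- length(clusters)
    if (k == 1) break
    reps <- vapply(clusters, min, "")
    best <- NULL
    best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- max(dm[clusters[[i]], clusters[[j]]])
        pair <- sort(c(reps[i], reps[j]))
        if (dij < best_d ||
            (dij == best_d && (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best_d <- dij
          best <- list(i = i, j = j, pair = pair)
        }
      }
    }
    if (best_d > threshold) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }

  clusters <- clusters[order(vapply(clusters, min, ""))]
  out <- list_rbind(imap(clusters, function(members, k) {
    tibble(read_id = sort(members), otu_id = sprintf("OTU_%04d", k))
  }))
  attr(out, "threshold") <- threshold
  out
}

#' Per-sample OTU counts
#'
#' @param clusters Tibble from [cluster_complete_linkage()].
#' @param samples Tibble `read_id`, `sample_id` (or a read tibble carrying
#'   `sample_id`).
#' @return Tibble `otu_id`, `sample_id`, `count`; total count equals the
#'   number of clustered reads.
#' @export
otu_counts <- function(clusters, samples) {
  clusters |>
    inner_join(select(samples, "read_id", "sample_id"), by = "read_id") |>
    count(.data$otu_id, .data$sample_id, name = "count")
}

#' Chao1 richness estimator
#'
#' Classic form `S_obs + F1^2 / (2 F2)`; bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where F1/F2 are singleton and
#' doubleton counts. When the classic form is requested with F2 = 0 and
#' F1 > 0 it falls back to the bias-corrected form with a warning. Always
#' >= S_obs.
#'
#' @param counts Non-negative integer OTU counts (one sample).
#' @param bias_corrected Use the bias-corrected form.
#' @return Estimated richness (double).
#' @export
chao1 <- function(counts, bias_corrected = FALSE) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (!bias_corrected && f2 == 0 && f1 > 0) {
    warn("F2 = 0; falling back to the bias-corrected Chao1")
    bias_corrected <- TRUE
  }
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f1 == 0) {
    s_obs
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Shannon diversity and Pielou evenness
#'
#' `H = -sum(p_i log p_i)` over positive counts (natural log by default, the
#' RDP convention) and `J = H / log(S_obs)`; J is defined as 0 for a single
#' OTU.
#'
#' @param counts Non-negative counts with at least one positive entry.
#' @param base Logarithm base.
#' @return One-row tibble with `shannon` and `pielou`.
#' @export
shannon_pielou <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) abort("all counts are zero")
  p <- counts / sum(counts)
  h <- -sum(p * log(p, base = base))
  s <- length(counts)
  tibble(shannon = h, pielou = if (s > 1) h / log(s, base = base) else 0)
}

#' Rarefaction curve (exact hypergeometric expectation)
#'
#' Expected number of OTUs observed in a random subsample of n reads,
#' `E[S(n)] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, evaluated via
#' [vegan::rarefy()]. The curve is monotone nondecreasing in n.
#'
#' @param counts Non-negative integer OTU counts (one sample).
#' @param depths Subsample sizes, each <= sum(counts).
#' @return Tibble `depth`, `expected_otus`.
#' @export
rarefaction <- function(counts, depths) {
  counts <- counts[counts > 0]
  if (any(depths > sum(counts))) abort("depth exceeds total count")
  if (any(depths < 1)) abort("depths must be >= 1")
  es <- as.numeric(vegan::rarefy(matrix(counts, nrow = 1), sample = depths))
  tibble(depth = as.integer(depths), expected_otus = es)
}

#' Alpha-diversity summary for one count vector
#'
#' @param counts Non-negative integer OTU counts (one sample, one threshold).
#' @return One-row tibble: `s_obs`, `f1`, `f2`, `chao1`, `chao1_bc`,
#'   `shannon`, `pielou`.
#' @export
diversity_summary <- function(counts) {
  counts <- counts[counts > 0]
  sp <- shannon_pielou(counts)
  tibble(
    s_obs = length(counts),
    f1 = sum(counts == 1),
    f2 = sum(counts == 2),
    chao1 = suppressWarnings(chao1(counts)),
    chao1_bc = chao1(counts, bias_corrected = TRUE),
    shannon = sp$shannon,
    pielou = sp$pielou
  )
}

#' Cluster and summarize diversity per sample at several thresholds
#'
#' Convenience wrapper reproducing the layout of a per-sample diversity
#' table: for each sample, reads are clustered at each threshold and
#' summarized with [diversity_summary()].
#'
#' @param reads Read tibble with `sample_id`.
#' @param thresholds Clustering distances (default the study's 0.03 and
#'   0.06).
#' @return Tibble with `sample_id`, `threshold`, `n_reads` and the
#'   [diversity_summary()] columns.
#' @export
diversity_table <- function(reads, thresholds = c(0.03, 0.06)) {
  reads |>
    group_by(.data$sample_id) |>
    group_modify(function(df, key) {
      dm <- pairwise_distance(df)
      list_rbind(map(thresholds, function(th) {
        cl <- cluster_complete_linkage(dm, th)
        counts <- as.integer(table(cl$otu_id))
        bind_cols(tibble(threshold = th, n_reads = nrow(df)),
                  diversity_summary(counts))
      }))
    }) |>
    ungroup()
}

#' Plot rarefaction curves
#'
#' @param curves Tibble with `depth`, `expected_otus` and optionally
#'   `sample_id`.
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curves) {
  aes_args <- if ("sample_id" %in% names(curves)) {
    ggplot2::aes(.data$depth, .data$expected_otus, colour = .data$sample_id)
  } else {
    ggplot2::aes(.data$depth, .data$expected_otus)
  }
  ggplot2::ggplot(curves, aes_args) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Reads sampled", y = "Expected OTUs",
                  colour = "Sample") +
    ggplot2::theme_minimal()
}
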