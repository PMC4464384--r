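TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Build training references from simulated genomes
#'
#' Splits each genome into `fragments_per_genome` non-overlapping training
#' sequences sharing the genome's lineage. The classifier's word prior
#' `(m + 0.5) / (M + 1)` is a per-genus word frequency estimated across
#' training sequences, so a genus needs several sequences for the prior to
#' be informative — reference databases provide many sequences per genus,
#' and fragmenting reproduces that structure here.
#'
#' @param genomes Genome tibble from [sim_genomes()].
#' @param fragments_per_genome Training sequences per genome (1 keeps whole
#'   genomes).
#' @return Tibble `seq_id`, `bases`, `lineage` (six ranks joined by `;`).
#' @export
as_training_refs <- function(genomes, fragments_per_genome = 25) {
  nf <- fragments_per_genome
  list_rbind(map(seq_len(nrow(genomes)), function(i) {
    b <- floor(seq(1, genomes$length[i] + 1, length.out = nf + 1))
    tibble(
      seq_id = sprintf("%s_frag%03d", genomes$genome_id[i], seq_len(nf)),
      bases = substring(genomes$bases[i], b[-length(b)], b[-1] - 1),
      lineage = paste(genomes$domain[i], genomes$phylum[i], genomes$class[i],
                      genomes$order[i], genomes$family[i], genomes$genus[i],
                      sep = ";")
    )
  }))
}

#' Train the naive-Bayes k-mer classifier
#'
#' The classifier of the RDP type: for word size `k`, each genus g gets a
#' word-presence prior `P(w | g) = (m(w) + 0.5) / (M + 1)`, where M is the
#' number of training sequences of that genus and m(w) how many of them
#' contain word w at least once. Words are the 4^k overlapping k-mers;
#' windows containing non-ACGT bases are skipped.
#'
#' @param refs Tibble with `bases` and `lineage`, the lineage a
#'   `domain;phylum;class;order;family;genus` string (complete to genus).
#' @param k Word size, 6-10 (default 8).
#' @return A `tax_model`: word log-probability matrix (4^k x genera), genus
#'   lineages and training counts.
#' @export
tax_train <- function(refs, k = 8) {
  if (k < 6 || k > 10) abort("k must be in [6, 10]")
  ranks <- stringr::str_split(refs$lineage, ";")
  if (any(lengths(ranks) != length(TAX_RANKS))) {
    abort("each lineage must have 6 ranks (domain;phylum;class;order;family;genus)")
  }
  lin <- do.call(rbind, ranks)
  colnames(lin) <- TAX_RANKS
  genus <- lin[, "genus"]

  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(refs$bases), width = k)
  presence <- counts > 0

  genera <- unique(genus)
  v <- 4L^k
  logp <- matrix(NA_real_, nrow = v, ncol = length(genera),
                 dimnames = list(NULL, genera))
  m_per <- integer(length(genera))
  for (gi in seq_along(genera)) {
    rows <- which(genus == genera[gi])
    m_per[gi] <- length(rows)
    m_w <- colSums(presence[rows, , drop = FALSE])
    logp[, gi] <- log((m_w + 0.5) / (m_per[gi] + 1))
  }

  lineages <- as_tibble(lin[!duplicated(genus), , drop = FALSE])
  lineages <- lineages[match(genera, lineages$genus), ]

  structure(
    list(k = k, logp = logp, genera = genera, m = m_per, lineages = lineages),
    class = "tax_model"
  )
}

#' @export
print.tax_model <- function(x, ...) {
  cat("<tax_model> k =", x$k, "-", length(x$genera), "genera,",
      sum(x$m), "training sequences\n")
  invisible(x)
}

# Integer word indices (1-based into the 4^k table) of the valid k-mers of a
# sequence; windows containing non-ACGT bases are dropped.
word_indices <- function(bases, k) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  v <- unname(code[strsplit(bases, "", fixed = TRUE)[[1]]])
  if (length(v) < k) return(integer(0))
  # sides = 1 convolution: coefficient j multiplies x[i - j + 1], so the
  # window's first base must get the highest power of 4
  w <- stats::filter(v, 4^(0:(k - 1)), sides = 1)
  w <- w[k:length(w)]
  as.integer(w[!is.na(w)]) + 1L
}

#' Classify reads with bootstrap confidence
#'
#' Scores each read's distinct words against every genus
#' (`score(g) = sum log P(w | g)`), on both strands, keeping the
#' better-scoring orientation. `n_bootstrap` trials each resample
#' `ceiling(W/8)` of the read's W distinct words with replacement and record
#' the winning genus; the confidence of each rank's taxon (taken from the
#' overall best genus's lineage) is the fraction of trials whose winner
#' shares that taxon. Fixed seeds give identical confidences. Reads with no
#' valid word (e.g. all N) are returned unclassified with confidence 0.
#'
#' @param model A [tax_train()] model.
#' @param reads Read tibble (length >= k).
#' @param n_bootstrap Bootstrap trials (default 100).
#' @param seed Optional integer seed (local to this call).
#' @return Long tibble: `read_id`, `rank`, `taxon`, `confidence`. Other read
#'   columns such as `sample_id` are carried along.
#' @export
tax_classify <- function(model, reads, n_bootstrap = 100, seed = NULL) {
  if (!inherits(model, "tax_model")) abort("model must be a tax_model")
  if (!is.null(seed)) withr::local_seed(seed)
  k <- model$k
  carry <- intersect(c("sample_id", "genome_id"), names(reads))

  res <- map(seq_len(nrow(reads)), function(i) {
    words_f <- unique(word_indices(reads$bases[i], k))
    words_r <- unique(word_indices(revcomp(reads$bases[i]), k))
    base_row <- tibble(read_id = reads$read_id[i], rank = TAX_RANKS)
    for (cc in carry) base_row[[cc]] <- reads[[cc]][i]
    if (length(words_f) == 0 && length(words_r) == 0) {
      return(mutate(base_row, taxon = NA_character_, confidence = 0))
    }
    score_f <- if (length(words_f)) colSums(model$logp[words_f, , drop = FALSE]) else -Inf
    score_r <- if (length(words_r)) colSums(model$logp[words_r, , drop = FALSE]) else -Inf
    words <- if (max(score_r) > max(score_f)) words_r else words_f
    scores <- if (max(score_r) > max(score_f)) score_r else score_f

    best <- which.max(scores)
    m <- ceiling(length(words) / 8)
    draw <- matrix(sample(words, m * n_bootstrap, replace = TRUE), nrow = m)
    winners <- vapply(seq_len(n_bootstrap), function(b) {
      which.max(colSums(model$logp[draw[, b], , drop = FALSE]))
    }, 1L)

    best_lineage <- unlist(model$lineages[best, TAX_RANKS])
    win_lineages <- as.matrix(model$lineages[winners, TAX_RANKS])
    conf <- vapply(seq_along(TAX_RANKS), function(r) {
      mean(win_lineages[, r] == best_lineage[r])
    }, 1)
    mutate(base_row, taxon = unname(best_lineage), confidence = conf)
  })
  list_rbind(res)
}

#' Rank-level relative-abundance summary
#'
#' Summarizes classifications at one rank using domain-assigned reads as the
#' 100% base (the convention of the source study's figures): a read counts
#' toward its rank taxon when its confidence there reaches `threshold`;
#' reads confident at the domain but not at the target rank are pooled as
#' `unclassified`. Reads not confidently assigned at the domain are excluded
#' from the base. Computed per sample when `sample_id` is present.
#'
#' @param assignments Long tibble from [tax_classify()].
#' @param rank One of phylum, class, order, family, genus.
#' @param threshold Confidence threshold (default 0.8, the RDP suggestion).
#' @return Tibble (`sample_id`,) `taxon`, `n_reads`, `percent`.
#' @export
summarize_ranks <- function(assignments, rank, threshold = 0.8) {
  if (!rank %in% setdiff(TAX_RANKS, "domain")) {
    abort("rank must be one of phylum, class, order, family, genus")
  }
  has_sample <- "sample_id" %in% names(assignments)
  grp <- if (has_sample) "sample_id" else character()

  wide <- assignments |>
    filter(.data$rank %in% c("domain", !!rank)) |>
    mutate(level = ifelse(.data$rank == "domain", "domain", "target")) |>
    select(dplyr::all_of(c("read_id", grp)), "level", "taxon", "confidence") |>
    tidyr::pivot_wider(names_from = "level",
                       values_from = c("taxon", "confidence"))

  wide <- wide |>
    filter(!is.na(.data$confidence_domain),
           .data$confidence_domain >= threshold) |>
    mutate(taxon = ifelse(.data$confidence_target >= threshold,
                          .data$taxon_target, "unclassified"))

  wide |>
    group_by(across(dplyr::all_of(grp))) |>
    mutate(.n_base = dplyr::n()) |>
    group_by(across(dplyr::all_of(c(grp, "taxon")))) |>
    summarise(n_reads = dplyr::n(),
              percent = 100 * dplyr::n() / dplyr::first(.data$.n_base),
              .groups = "drop") |>
    arrange(across(dplyr::all_of(grp)), dplyr::desc(.data$percent))
}

#' Top-n taxa per sample
#'
#' Extracts the `n` most abundant named taxa per sample from a
#' [summarize_ranks()] table (e.g. the top 10 genera for ribbon plots).
#'
#' @param rank_summary Output of [summarize_ranks()].
#' @param n Number of taxa to keep per sample.
#' @return Filtered tibble in descending abundance order.
#' @export
top_taxa <- function(rank_summary, n = 10) {
  grp <- intersect("sample_id", names(rank_summary))
  rank_summary |>
    filter(.data$taxon != "unclassified") |>
    group_by(across(dplyr::all_of(grp))) |>
    slice_max(.data$percent, n = n, with_ties = FALSE) |>
    ungroup()
}
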