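#' Simulate reference genomes with planted single-copy marker loci
#'
#' Generates a small community of bacterial reference genomes as order-0
#' Markov chains (i.i.d. bases) with per-genome GC content. GC contents are
#' spread evenly across `gc_range` so that tetranucleotide composition
#' separates the genomes (adjacent genomes differ by >= 8% GC at the
#' defaults). Each genome carries `n_markers` non-overlapping single-copy
#' marker loci (a stand-in for essential single-copy genes such as the
#' 105-gene alphaproteobacterial set), placed evenly along the sequence and
#' recorded as 1-based inclusive coordinates.
#'
#' Each genome is given its own six-rank lineage (domain Bacteria; distinct
#' phylum..genus), so classifier tests have unambiguous truth.
#'
#' @param n Number of genomes.
#' @param lengths Integer vector of genome lengths (bp); recycled. Default
#'   spreads evenly over 0.5-1 Mb.
#' @param gc_range Range of GC contents across genomes.
#' @param n_markers Marker loci per genome.
#' @param marker_length Length of each marker locus (bp); loci model the
#'   conserved detectable anchor span of a single-copy gene, sized so marker
#'   recovery on assembly-scale contigs matches the ~95% completeness regime
#'   of deeply covered bins.
#' @param marker_set A marker set from [marker_set()]; its ids label the loci.
#' @param seed Optional integer seed (local to this call).
#' @return A genome tibble: `genome_id`, `bases`, `length`, `gc`,
#'   `domain`..`genus`, and a `marker_loci` list-column of tibbles
#'   (`marker_id`, `start`, `end`).
#' @export
#' @examples
#' g <- sim_genomes(n = 2, lengths = 5e4, n_markers = 10, seed = 1)
#' g$length
sim_genomes <- function(n = 5,
                        lengths = NULL,
                        gc_range = c(0.35, 0.67),
                        n_markers = 105,
                        marker_length = 500,
                        marker_set = dwbiofilm::marker_set(n_markers),
                        seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(n >= 1)
  if (is.null(lengths)) {
    lengths <- round(seq(5e5, 1e6, length.out = n))
  }
  lengths <- as.integer(rep_len(lengths, n))
  gc <- if (n == 1) mean(gc_range) else seq(gc_range[1], gc_range[2], length.out = n)
  if (n > 1 && min(diff(sort(gc))) < 0.08 - 1e-9) {
    warn("GC gap between genomes is below 0.08; composition-based separation may be weak")
  }
  if (length(marker_set$marker_ids) < n_markers) {
    abort("marker_set has fewer ids than n_markers")
  }
  ids <- sprintf("genome_%02d", seq_len(n))
  tag <- toupper(letters[seq_len(n)])

  bases <- map_chr(seq_len(n), function(i) random_dna(lengths[i], gc[i]))

  marker_loci <- map(seq_len(n), function(i) {
    len <- lengths[i]
    if (n_markers == 0) {
      return(tibble(marker_id = character(), start = integer(), end = integer()))
    }
    if (n_markers * marker_length > len) {
      abort("genome too short to host the requested marker loci")
    }
    # even placement, non-overlapping by construction
    gap <- (len - n_markers * marker_length) / (n_markers + 1)
    start <- as.integer(round((seq_len(n_markers) - 1) * (marker_length + gap) + gap + 1))
    tibble(marker_id = marker_set$marker_ids[seq_len(n_markers)],
           start = start, end = start + marker_length - 1L)
  })

  tibble(
    genome_id = ids,
    bases = bases,
    length = lengths,
    gc = gc,
    domain = "Bacteria",
    phylum = paste0("Phylum_", tag),
    class = paste0("Class_", tag),
    order = paste0("Order_", tag),
    family = paste0("Family_", tag),
    genus = paste0("Genus_", tag),
    marker_loci = marker_loci
  )
}

#' Declare a single-copy marker set
#'
#' A marker set is a named collection of genes expected exactly once per
#' genome; completeness and redundancy of a genome bin are scored against it.
#' The default mirrors the size of the essential single-copy gene (ESCG) set
#' used for alphaproteobacterial bins (105 genes).
#'
#' @param n Number of markers.
#' @param set_id Identifier for the set.
#' @return A list with `set_id` and unique `marker_ids`.
#' @export
marker_set <- function(n = 105, set_id = paste0("escg", n)) {
  ids <- sprintf("ESCG_%03d", seq_len(n))
  stopifnot(!anyDuplicated(ids))
  list(set_id = set_id, marker_ids = ids)
}

#' Describe a shotgun sequencing experiment over a community
#'
#' Bundles the community abundance structure with library parameters
#' (fragment size distribution, read length, substitution error rate) and
#' validates them. Per-genome expected fold-coverage is
#' `abundance * total_bases / genome_length`.
#'
#' @param genomes Genome tibble from [sim_genomes()].
#' @param abundances Numeric relative abundances, one per genome (sum to 1);
#'   either named by `genome_id` or in genome order.
#' @param total_bases Total bases to simulate across all reads.
#' @param fragment_length_mean,fragment_length_sd Fragment size (bp); the
#'   study's library targeted ~180 bp fragments sequenced as 100 bp pairs.
#' @param read_length Read length (bp).
#' @param error_rate Per-base substitution probability.
#' @return A `community_design` object (list) with an `abundance` tibble
#'   (`genome_id`, `abundance`, `fold_coverage`) and the library parameters.
#' @export
community_design <- function(genomes,
                             abundances,
                             total_bases,
                             fragment_length_mean = 180,
                             fragment_length_sd = 20,
                             read_length = 100,
                             error_rate = 0.001) {
  if (!is.null(names(abundances))) {
    missing <- setdiff(names(abundances), genomes$genome_id)
    if (length(missing)) {
      abort(paste0("abundance given for unknown genome_id: ",
                   paste(missing, collapse = ", ")))
    }
    abundances <- abundances[genomes$genome_id]
    if (anyNA(abundances)) abort("abundances must cover every genome")
  }
  if (length(abundances) != nrow(genomes)) {
    abort("need one abundance per genome")
  }
  if (any(abundances < 0)) abort("abundances must be >= 0")
  if (abs(sum(abundances) - 1) > 1e-9) abort("abundances must sum to 1")
  if (read_length > fragment_length_mean + 4 * fragment_length_sd) {
    abort("read_length exceeds fragment mean + 4 sd")
  }
  ab <- tibble(
    genome_id = genomes$genome_id,
    abundance = unname(abundances),
    fold_coverage = unname(abundances) * total_bases / genomes$length
  )
  structure(
    list(abundance = ab,
         total_bases = total_bases,
         fragment_length_mean = fragment_length_mean,
         fragment_length_sd = fragment_length_sd,
         read_length = read_length,
         error_rate = error_rate),
    class = "community_design"
  )
}

#' @export
print.community_design <- function(x, ...) {
  cat("<community_design> ", nrow(x$abundance), " genomes, ",
      format(x$total_bases, big.mark = ","), " bp total, ",
      x$read_length, " bp reads, fragments ~N(",
      x$fragment_length_mean, ", ", x$fragment_length_sd, "), error rate ",
      x$error_rate, "\n", sep = "")
  print(x$abundance)
  invisible(x)
}

#' Simulate paired-end shotgun reads with a true-origin table
#'
#' Draws `round(total_bases / (2 * read_length))` fragments, assigns each to
#' a genome by the design abundances (multinomial), places it uniformly on a
#' random strand, and reads `read_length` bases inward from both fragment
#' ends. Fragments shorter than the read length yield truncated pairs,
#' flagged in the origin table. Substitution errors are applied at
#' `error_rate`; qualities are Phred+33 draws from Normal(35, 4) clipped to
#' [2, 40]. Identical seeds give identical output.
#'
#' @param design A [community_design()].
#' @param genomes Genome tibble from [sim_genomes()].
#' @param seed Optional integer seed (local to this call).
#' @return A list with `pairs` (tibble: `pair_id`, `fwd`, `fwd_quality`,
#'   `rev`, `rev_quality`, `truncated`) and `origin` (tibble: `pair_id`,
#'   `genome_id`, `start`, `end`, `strand`, `fragment_length`). `start`/`end`
#'   are 1-based inclusive genome coordinates of the fragment.
#' @export
simulate_shotgun <- function(design, genomes, seed = NULL) {
  if (!inherits(design, "community_design")) abort("design must be a community_design")
  if (nrow(genomes) == 0) abort("empty genome list")
  if (!is.null(seed)) withr::local_seed(seed)

  rl <- design$read_length
  n_pairs <- max(1L, round(design$total_bases / (2 * rl)))
  gi <- sample.int(nrow(genomes), n_pairs, replace = TRUE,
                   prob = design$abundance$abundance)
  glen <- genomes$length[gi]

  L <- as.integer(round(stats::rnorm(n_pairs, design$fragment_length_mean,
                                     design$fragment_length_sd)))
  L <- pmax(20L, pmin(L, glen))
  start <- as.integer(floor(stats::runif(n_pairs, 1, glen - L + 1 + 1)))
  start <- pmin(start, glen - L + 1L)
  end <- start + L - 1L
  strand <- sample(c("+", "-"), n_pairs, replace = TRUE)

  frag <- substring(genomes$bases[gi], start, end)
  minus <- strand == "-"
  if (any(minus)) frag[minus] <- revcomp(frag[minus])

  rlen <- pmin(rl, L)
  fwd <- substring(frag, 1L, rlen)
  rev <- revcomp(substring(frag, L - rlen + 1L, L))

  if (design$error_rate > 0) {
    fwd <- apply_substitutions(fwd, design$error_rate)
    rev <- apply_substitutions(rev, design$error_rate)
  }
  fq <- quality_strings(rlen)
  rq <- quality_strings(rlen)

  pair_id <- sprintf("pair_%07d", seq_len(n_pairs))
  list(
    pairs = tibble(pair_id = pair_id, fwd = fwd, fwd_quality = fq,
                   rev = rev, rev_quality = rq, truncated = L < rl),
    origin = tibble(pair_id = pair_id, genome_id = genomes$genome_id[gi],
                    start = start, end = end, strand = strand,
                    fragment_length = L)
  )
}

# Vectorised substitution errors: only reads drawn to contain >= 1 error are
# touched, so the common case stays cheap.
apply_substitutions <- function(reads, error_rate) {
  n_err <- stats::rbinom(length(reads), nchar(reads), error_rate)
  idx <- which(n_err > 0L)
  alt <- c("A", "C", "G", "T")
  for (i in idx) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(ch), n_err[i])
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(alt, b), 1L), "")
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

# One Phred+33 quality string per requested length.
quality_strings <- function(lengths, mean = 35, sd = 4) {
  q <- pmin(40L, pmax(2L, as.integer(round(stats::rnorm(sum(lengths), mean, sd)))))
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  vapply(seq_along(lengths),
         function(i) intToUtf8(q[starts[i]:ends[i]] + 33L), "")
}

#' Simulate assembled contigs with coverage labels
#'
#' Tiles each genome end-to-end into contigs with lengths drawn uniformly
#' from `contig_length_range`, standing in for a de novo assembly of a
#' deeply sequenced community. Each contig's mean fold-coverage is its
#' genome's expected fold-coverage times multiplicative lognormal noise
#' (`sdlog = noise_sd`; `noise_sd = 0` gives the exact genome coverage). The
#' true genome and coordinates are recorded for use as an oracle.
#'
#' @param genomes Genome tibble.
#' @param design Optional [community_design()] supplying per-genome
#'   fold-coverage; alternatively pass `coverage`, a vector named by
#'   `genome_id`.
#' @param coverage Named numeric per-genome fold-coverage (used when `design`
#'   is NULL).
#' @param contig_length_range Min/max contig length (bp). Lengths below the
#'   downstream 300 bp filter are permitted deliberately, so filter behaviour
#'   can be tested.
#' @param noise_sd Lognormal sdlog of the coverage noise.
#' @param seed Optional integer seed.
#' @return Contig tibble: `contig_id`, `genome_id`, `bases`, `length`,
#'   `coverage`, `start`, `end` (1-based inclusive genome coordinates).
#' @export
simulate_contigs <- function(genomes, design = NULL, coverage = NULL,
                             contig_length_range = c(500, 20000),
                             noise_sd = 0.15, seed = NULL) {
  if (is.null(genomes) || nrow(genomes) == 0) abort("empty genome list")
  if (!is.null(seed)) withr::local_seed(seed)
  if (!is.null(design)) {
    coverage <- stats::setNames(design$abundance$fold_coverage,
                                design$abundance$genome_id)
  }
  if (is.null(coverage)) abort("supply design or coverage")
  missing <- setdiff(genomes$genome_id, names(coverage))
  if (length(missing)) abort("coverage missing for some genomes")

  out <- map(seq_len(nrow(genomes)), function(i) {
    len <- genomes$length[i]
    # draw generous number of lengths, then cut at the genome end
    sizes <- as.integer(round(stats::runif(
      ceiling(len / contig_length_range[1]) + 1L,
      contig_length_range[1], contig_length_range[2])))
    ends <- cumsum(sizes)
    k <- which(ends >= len)[1]
    sizes <- sizes[seq_len(k)]
    ends <- ends[seq_len(k)]
    ends[k] <- len
    starts <- c(1L, utils::head(ends, -1) + 1L)
    keep <- ends - starts + 1L >= 4L
    starts <- starts[keep]; ends <- ends[keep]
    cov <- coverage[[genomes$genome_id[i]]] *
      if (noise_sd > 0) stats::rlnorm(length(starts), 0, noise_sd) else 1
    tibble(
      contig_id = sprintf("%s_ctg_%04d", genomes$genome_id[i], seq_along(starts)),
      genome_id = genomes$genome_id[i],
      bases = substring(genomes$bases[i], starts, ends),
      length = ends - starts + 1L,
      coverage = cov,
      start = starts,
      end = ends
    )
  })
  list_rbind(out)
}

#' Simulate barcoded 16S-style amplicon reads
#'
#' Emits per-sample single-end reads of the form
#' `barcode + forward primer + insert [+ revcomp(reverse primer)]`, emulating
#' 454 amplicon libraries of a V3-V4-like region. Insert lengths are
#' Normal(`length_mean`, `length_sd`) truncated at 200 bp; inserts are
#' genome substrings chosen by the per-sample genome abundances. Degenerate
#' primer positions are instantiated with a random allowed base per read.
#' Substitution errors apply to the insert only (barcode/primer synthesis is
#' treated as exact); qualities cover the whole read.
#'
#' @param genomes Genome tibble.
#' @param n_per_sample Reads per sample.
#' @param barcodes Named character vector: `sample_id -> barcode`. Barcodes
#'   must be unique and of equal length.
#' @param primer_fwd Forward primer (plain bases).
#' @param primer_rev Optional character vector of reverse primers (IUPAC
#'   codes allowed); one is drawn per read and appended reverse-complemented.
#' @param length_mean,length_sd Insert length distribution (bp); defaults
#'   match a 438 +/- 16 bp cleaned-read profile.
#' @param abundances Per-genome composition, either a single named vector
#'   (all samples) or a list keyed by sample_id. Default: uniform.
#' @param error_rate Substitution probability per insert base.
#' @param seed Optional integer seed.
#' @return Read tibble with `read_id`, `sample_id` (truth), `genome_id`
#'   (truth), `bases`, `quality`.
#' @export
simulate_amplicons <- function(genomes, n_per_sample, barcodes,
                               primer_fwd, primer_rev = NULL,
                               length_mean = 438, length_sd = 16,
                               abundances = NULL, error_rate = 0.005,
                               seed = NULL) {
  if (anyDuplicated(barcodes)) abort("duplicate barcode")
  if (is.null(names(barcodes)) || anyDuplicated(names(barcodes))) {
    abort("barcodes must be uniquely named by sample_id")
  }
  if (!nzchar(primer_fwd)) abort("primer_fwd must be non-empty")
  if (!is.null(seed)) withr::local_seed(seed)

  samples <- names(barcodes)
  out <- map(samples, function(s) {
    if (n_per_sample == 0) {
      return(seq_tbl(character(), character(), character(),
                     sample_id = character(), genome_id = character()))
    }
    ab <- if (is.list(abundances)) abundances[[s]] else abundances
    p <- rep(1 / nrow(genomes), nrow(genomes))
    if (!is.null(ab)) {
      p <- rep(0, nrow(genomes))
      p[match(names(ab), genomes$genome_id)] <- ab
    }
    gi <- sample.int(nrow(genomes), n_per_sample, replace = TRUE, prob = p)
    L <- pmax(200L, as.integer(round(stats::rnorm(n_per_sample, length_mean, length_sd))))
    L <- pmin(L, genomes$length[gi])
    start <- as.integer(floor(stats::runif(n_per_sample, 1, genomes$length[gi] - L + 2)))
    insert <- substring(genomes$bases[gi], start, start + L - 1L)
    if (error_rate > 0) insert <- apply_substitutions(insert, error_rate)
    tail_seq <- ""
    if (!is.null(primer_rev)) {
      tail_seq <- revcomp(vapply(
        sample(primer_rev, n_per_sample, replace = TRUE), instantiate_iupac, ""))
    }
    bases <- paste0(barcodes[[s]], primer_fwd, insert, tail_seq)
    seq_tbl(sprintf("%s_read_%06d", s, seq_len(n_per_sample)),
            bases, quality_strings(nchar(bases)),
            sample_id = s, genome_id = genomes$genome_id[gi])
  })
  list_rbind(out)
}

# Replace IUPAC ambiguity codes by one random allowed base each.
instantiate_iupac <- function(p) {
  ch <- strsplit(p, "", fixed = TRUE)[[1]]
  amb <- which(!ch %in% c("A", "C", "G", "T"))
  for (i in amb) ch[i] <- sample(IUPAC_SETS[[ch[i]]], 1L)
  paste(ch, collapse = "")
}

#' Count marker-locus copies contained in a contig set
#'
#' For every marker locus declared on the reference genomes, counts how many
#' member contigs fully contain it (same genome, `contig start <= locus
#' start` and `locus end <= contig end`). Duplicated contigs therefore yield
#' copy counts above 1; absent markers are reported with count 0. This
#' stands in for homology-based marker detection; real-data users supply an
#' externally produced hit table in the same two-column layout.
#'
#' @param contigs Contig tibble with truth columns `genome_id`, `start`,
#'   `end` (e.g. from [simulate_contigs()] or a [genome_bin]).
#' @param genomes Genome tibble with `marker_loci`.
#' @return Tibble `marker_id`, `copies` covering every marker in `genomes`.
#' @export
emit_marker_hits <- function(contigs, genomes) {
  if (inherits(contigs, "genome_bin")) contigs <- contigs$contigs
  loci <- genomes |>
    select("genome_id", "marker_loci") |>
    tidyr::unnest("marker_loci")
  if (nrow(loci) == 0) {
    return(tibble(marker_id = character(), copies = integer()))
  }
  hits <- inner_join(loci,
                     select(contigs, "genome_id",
                            contig_start = "start", contig_end = "end"),
                     by = "genome_id", relationship = "many-to-many") |>
    filter(.data$contig_start <= .data$start, .data$end <= .data$contig_end) |>
    count(.data$marker_id, name = "copies")
  tibble(marker_id = unique(loci$marker_id)) |>
    left_join(hits, by = "marker_id") |>
    mutate(copies = as.integer(tidyr::replace_na(.data$copies, 0L)))
}

#' The default binning study community
#'
#' The community regime the binning workflow targets: five genomes of
#' 0.5-1 Mb, one dominant organism at 28% relative abundance whose
#' fold-coverage sits at ~450x inside the 300-600x selection window, the
#' remaining four sharing 72% with coverages below the window (with
#' multiplicative coverage noise a few of their contigs leak in, providing
#' realistic contamination for the composition filter to remove). Total
#' sequencing depth is set so the dominant genome's expected coverage is
#' exactly 450x.
#'
#' @param seed Integer seed for genome generation.
#' @param n Number of genomes.
#' @param dominant_abundance Relative abundance of the dominant genome.
#' @param dominant_coverage Target fold-coverage of the dominant genome.
#' @return List: `genomes`, `design` ([community_design()]), `dominant`
#'   (genome_id of the planted genome).
#' @export
sim_binning_community <- function(seed = NULL, n = 5,
                                  dominant_abundance = 0.28,
                                  dominant_coverage = 450) {
  genomes <- sim_genomes(n = n, seed = seed)
  # dominant = smallest genome, so the others' coverage stays below the window
  dom <- which.min(genomes$length)
  total <- dominant_coverage * genomes$length[dom] / dominant_abundance
  ab <- rep((1 - dominant_abundance) / (n - 1), n)
  ab[dom] <- dominant_abundance
  list(genomes = genomes,
       design = community_design(genomes, ab, total),
       dominant = genomes$genome_id[dom])
}

#' Simulate cluster-structured functional profiles
#'
#' Generates samples-by-category count profiles with a declared ecosystem
#' label per sample, for exercising profile normalization and PCA. Each
#' ecosystem has its own category-weight vector; samples scatter around it
#' with within-cluster noise, and cluster centres are `separation`
#' within-cluster standard deviations apart in the latent (log-weight)
#' space.
#'
#' @param samples_per_cluster Integer vector, samples per ecosystem.
#' @param n_categories Number of functional categories.
#' @param separation Cluster-centre separation in units of within-cluster sd.
#' @param depth Total counts per sample.
#' @param seed Optional integer seed.
#' @return Tibble with `sample_id`, `ecosystem` and one count column per
#'   category (`cat_01`, ...).
#' @export
sim_profiles <- function(samples_per_cluster = c(10, 10, 10),
                         n_categories = 25, separation = 8, depth = 1e5,
                         seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  k <- length(samples_per_cluster)
  sd_within <- 0.15
  centres <- matrix(stats::rnorm(k * n_categories, 0, separation * sd_within / sqrt(2)),
                    nrow = k)
  rows <- map(seq_len(k), function(c) {
    n <- samples_per_cluster[c]
    lat <- matrix(stats::rnorm(n * n_categories, 0, sd_within), nrow = n)
    lat <- sweep(lat, 2, centres[c, ], `+`)
    w <- exp(lat)
    w <- w / rowSums(w)
    counts <- t(apply(w, 1, function(p) stats::rmultinom(1, depth, p)[, 1]))
    colnames(counts) <- sprintf("cat_%02d", seq_len(n_categories))
    bind_cols(tibble(ecosystem = sprintf("ecosystem_%d", c)), as_tibble(counts))
  })
  out <- list_rbind(rows)
  bind_cols(tibble(sample_id = sprintf("sample_%02d", seq_len(nrow(out)))), out)
}
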