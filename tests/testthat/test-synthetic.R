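test_that("sim_genomes is reproducible and respects its declared structure", {
  g1 <- sim_genomes(n = 3, lengths = c(5e4, 6e4, 7e4), n_markers = 20,
                    marker_set = marker_set(20), seed = 11)
  g2 <- sim_genomes(n = 3, lengths = c(5e4, 6e4, 7e4), n_markers = 20,
                    marker_set = marker_set(20), seed = 11)
  expect_identical(g1, g2)
  expect_identical(nchar(g1$bases), g1$length)
  # empirical GC tracks the declared GC
  emp_gc <- vapply(g1$bases, function(b) {
    mean(strsplit(b, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  }, 1, USE.NAMES = FALSE)
  expect_true(all(abs(emp_gc - g1$gc) < 0.02))
  # distinct genus labels, one lineage per genome
  expect_identical(anyDuplicated(g1$genus), 0L)
})

test_that("sim_genomes warns when GC gaps fall below 0.08", {
  expect_warning(sim_genomes(n = 3, lengths = 2e4, gc_range = c(0.40, 0.50),
                             n_markers = 10, marker_set = marker_set(10),
                             seed = 1),
                 "GC gap")
  expect_silent(g <- sim_genomes(n = 2, lengths = 2e4,
                                 gc_range = c(0.40, 0.48), n_markers = 10,
                                 marker_set = marker_set(10), seed = 1))
})

test_that("marker loci lie inside the genome and match marker_length", {
  g <- sim_genomes(n = 2, lengths = c(8e4, 9e4), n_markers = 20,
                   marker_length = 500,
                   marker_set = marker_set(20), seed = 3)
  for (i in 1:2) {
    loci <- g$marker_loci[[i]]
    expect_identical(nrow(loci), 20L)
    expect_identical(anyDuplicated(loci$marker_id), 0L)
    expect_true(all(loci$start >= 1))
    expect_true(all(loci$end <= g$length[i]))
    expect_true(all(loci$end - loci$start + 1 == 500))
    expect_true(all(diff(loci$start) > 0))
  }
})

test_that("community_design validates abundances and computes fold coverage", {
  g <- sim_genomes(n = 2, lengths = c(1e4, 2e4), gc_range = c(0.4, 0.6),
                   n_markers = 5, marker_set = marker_set(5), seed = 4)
  d <- community_design(g, c(0.25, 0.75), total_bases = 4e5)
  expect_s3_class(d, "community_design")
  expect_equal(d$abundance$fold_coverage, c(0.25 * 4e5 / 1e4, 0.75 * 4e5 / 2e4))
  expect_error(community_design(g, c(0.5, 0.4), 4e5))
  expect_error(community_design(g, c(nope = 1), 4e5), "unknown genome_id")
})

test_that("simulate_shotgun origins reconstruct the error-free reads exactly", {
  g <- sim_genomes(n = 2, lengths = c(3e4, 4e4), gc_range = c(0.4, 0.6),
                   n_markers = 5, marker_set = marker_set(5), seed = 5)
  d <- community_design(g, c(0.5, 0.5), total_bases = 6e4, error_rate = 0)
  sim <- simulate_shotgun(d, g, seed = 6)
  expect_identical(sim$pairs$pair_id, sim$origin$pair_id)
  idx <- match(sim$origin$genome_id, g$genome_id)
  for (i in seq_len(nrow(sim$pairs))) {
    frag <- substr(g$bases[idx[i]], sim$origin$start[i], sim$origin$end[i])
    if (sim$origin$strand[i] == "-") frag <- revcomp(frag)
    L <- nchar(frag)
    rl <- nchar(sim$pairs$fwd[i])
    expect_identical(sim$pairs$fwd[i], substr(frag, 1, rl))
    expect_identical(sim$pairs$rev[i], revcomp(substr(frag, L - rl + 1, L)))
  }
  expect_identical(nchar(sim$pairs$fwd), nchar(sim$pairs$fwd_quality))
})

test_that("simulate_shotgun with errors stays close to the error rate", {
  g <- sim_genomes(n = 1, lengths = 3e4, n_markers = 5,
                   marker_set = marker_set(5), seed = 7)
  d <- community_design(g, 1, total_bases = 4e5, error_rate = 0.01)
  sim <- simulate_shotgun(d, g, seed = 8)
  idx <- match(sim$origin$genome_id, g$genome_id)
  mm <- vapply(seq_len(nrow(sim$pairs)), function(i) {
    frag <- substr(g$bases[idx[i]], sim$origin$start[i], sim$origin$end[i])
    if (sim$origin$strand[i] == "-") frag <- revcomp(frag)
    rl <- nchar(sim$pairs$fwd[i])
    truth <- substr(frag, 1, rl)
    sum(strsplit(sim$pairs$fwd[i], "")[[1]] != strsplit(truth, "")[[1]]) / rl
  }, 1)
  # binomial(100, 0.01) per read; mean over ~2000 reads is tight
  expect_gt(mean(mm), 0.005)
  expect_lt(mean(mm), 0.015)
})

test_that("simulate_contigs tiles the genome and honours noise_sd = 0", {
  g <- sim_genomes(n = 1, lengths = 5e4, n_markers = 5,
                   marker_set = marker_set(5), seed = 9)
  ctg <- simulate_contigs(g, coverage = c(genome_01 = 450),
                          contig_length_range = c(500, 5000),
                          noise_sd = 0, seed = 10)
  expect_true(all(ctg$coverage == 450))
  expect_identical(ctg$bases,
                   substring(g$bases, ctg$start, ctg$end))
  # end-to-end tiling: contiguous, non-overlapping, covers the genome
  expect_identical(ctg$start, c(1L, utils::head(ctg$end, -1) + 1L))
  expect_identical(ctg$end[nrow(ctg)], g$length)
  expect_identical(sum(ctg$length), g$length)
})

test_that("emit_marker_hits counts full containment only", {
  g <- sim_genomes(n = 1, lengths = 2e4, n_markers = 4, marker_length = 100,
                   marker_set = marker_set(4), seed = 12)
  loci <- g$marker_loci[[1]]
  # contig containing marker 1 exactly, one cutting marker 2 in half,
  # and two copies containing marker 3
  contigs <- tibble::tibble(
    genome_id = "genome_01",
    start = c(loci$start[1], loci$start[2] + 50, loci$start[3] - 5,
              loci$start[3] - 5),
    end = c(loci$end[1], loci$end[2] + 50, loci$end[3] + 5, loci$end[3] + 5)
  )
  hits <- emit_marker_hits(contigs, g)
  expect_identical(sort(hits$marker_id), sort(loci$marker_id))
  got <- stats::setNames(hits$copies, hits$marker_id)
  expect_identical(got[["ESCG_001"]], 1L)
  expect_identical(got[["ESCG_002"]], 0L)
  expect_identical(got[["ESCG_003"]], 2L)
  expect_identical(got[["ESCG_004"]], 0L)
})

test_that("whole-genome contig set recovers every marker (100% completeness)", {
  g <- sim_genomes(n = 1, lengths = 5e4, n_markers = 10,
                   marker_set = marker_set(10), seed = 13)
  whole <- tibble::tibble(genome_id = g$genome_id, start = 1L, end = g$length)
  sc <- score_bin(emit_marker_hits(whole, g), marker_set(10))
  expect_equal(sc$completeness, 100)
  expect_equal(sc$redundancy, 0)
})

test_that("simulate_amplicons emits barcode+primer reads with truth labels", {
  g <- sim_genomes(n = 2, lengths = c(2e4, 3e4), gc_range = c(0.4, 0.6),
                   n_markers = 5, marker_set = marker_set(5), seed = 14)
  bc <- c(s1 = "ACGTACGT", s2 = "TGCATGCA")
  reads <- simulate_amplicons(g, n_per_sample = 20, barcodes = bc,
                              primer_fwd = "AGAGTTTGATCCTGGCTCAG",
                              length_mean = 300, length_sd = 10,
                              error_rate = 0, seed = 15)
  expect_identical(nrow(reads), 40L)
  expect_identical(sort(unique(reads$sample_id)), c("s1", "s2"))
  expect_true(all(substr(reads$bases, 1, 8) == bc[reads$sample_id]))
  expect_true(all(substr(reads$bases, 9, 28) == "AGAGTTTGATCCTGGCTCAG"))
  expect_identical(nchar(reads$bases), nchar(reads$quality))
  # error-free inserts are genome substrings
  ins <- substr(reads$bases, 29, nchar(reads$bases))
  gi <- match(reads$genome_id, g$genome_id)
  hit <- vapply(seq_along(ins),
                function(i) grepl(ins[i], g$bases[gi[i]], fixed = TRUE), TRUE)
  expect_true(all(hit))
})

test_that("sim_profiles emits labelled count profiles of the requested shape", {
  pr <- sim_profiles(samples_per_cluster = c(4, 4), n_categories = 10,
                     depth = 1e4, seed = 16)
  expect_identical(nrow(pr), 8L)
  expect_identical(sum(startsWith(names(pr), "cat_")), 10L)
  expect_true(all(rowSums(pr[, startsWith(names(pr), "cat_")]) == 1e4))
  expect_identical(length(unique(pr$ecosystem)), 2L)
})
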