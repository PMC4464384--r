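test_that("pairwise_distance: identity, scattered mismatches, containment", {
  set.seed(41)
  s <- rand_dna(100)
  s3 <- mutate_positions(s, c(20, 50, 80))  # 3 scattered internal mismatches
  reads <- seq_tbl(c("a", "b", "c", "d"),
                   c(s, s, s3, substr(s, 11, 90)))
  d <- pairwise_distance(reads)
  expect_identical(dimnames(d), list(reads$read_id, reads$read_id))
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 3 / 100)
  # a subsequence aligns with free terminal gaps: distance 0
  expect_equal(d["a", "d"], 0)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("pairwise_distance aligned mode: column rule with terminal gaps", {
  reads <- seq_tbl(c("a", "b", "c"),
                   c("--ACGTACGT", "TTACGTACGA", "TTACG-ACGA"))
  d <- pairwise_distance(reads, mode = "aligned")
  # a vs b: terminal gap columns 1-2 excluded; 1 mismatch over 8 columns
  expect_equal(d["a", "b"], 1 / 8)
  # b vs c: internal gap counts as mismatch; 1 gap over 10 columns
  expect_equal(d["b", "c"], 1 / 10)
  expect_error(pairwise_distance(seq_tbl(c("a", "b"), c("AC", "ACG")),
                                 mode = "aligned"), "equal-length")
})

test_that("complete linkage reproduces the hand-worked example", {
  dm <- matrix(c(0, 0.02, 0.05,
                 0.02, 0, 0.04,
                 0.05, 0.04, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- cluster_complete_linkage(dm, 0.03)
  expect_identical(attr(cl, "threshold"), 0.03)
  grp <- split(cl$read_id, cl$otu_id)
  expect_identical(unname(grp), list(c("A", "B"), "C"))
})

test_that("complete linkage output is valid and maximal (brute-force oracle)", {
  set.seed(42)
  for (trial in 1:3) {
    n <- 8
    dm <- matrix(0, n, n)
    dm[upper.tri(dm)] <- round(stats::runif(n * (n - 1) / 2, 0, 0.1), 3)
    dm <- dm + t(dm)
    ids <- sprintf("r%02d", 1:n)
    dimnames(dm) <- list(ids, ids)
    th <- 0.05
    cl <- cluster_complete_linkage(dm, th)
    blocks <- lapply(split(cl$read_id, cl$otu_id), function(m) match(m, ids))
    # every OTU satisfies max intra distance <= threshold
    expect_true(partition_valid(blocks, dm, th))
    # maximal: no two OTUs can merge and stay within the threshold
    k <- length(blocks)
    if (k > 1) {
      for (i in 1:(k - 1)) {
        for (j in (i + 1):k) {
          expect_gt(max(dm[blocks[[i]], blocks[[j]]]), th)
        }
      }
    }
    # the partition appears among all valid partitions (exhaustive check)
    valid <- Filter(function(p) partition_valid(p, dm, th), all_partitions(n))
    canon <- function(p) paste(sort(vapply(p, function(b)
      paste(sort(b), collapse = ","), "")), collapse = "|")
    expect_true(canon(blocks) %in% vapply(valid, canon, ""))
  }
})

test_that("every read appears exactly once and clustering at 0 is injective on distinct reads", {
  dm <- matrix(c(0, 0.01, 0.01, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  cl0 <- cluster_complete_linkage(dm, 0)
  expect_identical(length(unique(cl0$otu_id)), 2L)
  cl1 <- cluster_complete_linkage(dm, 0.01)
  expect_identical(length(unique(cl1$otu_id)), 1L)
  expect_identical(sort(cl1$read_id), c("x", "y"))
})

test_that("chao1 matches hand calculation and vegan", {
  counts <- c(rep(1, 4), rep(2, 2), rep(5, 4))  # S=10, F1=4, F2=2
  expect_equal(chao1(counts), 10 + 16 / 4)                 # 14
  expect_equal(chao1(counts, bias_corrected = TRUE),
               10 + 4 * 3 / (2 * 3))                       # 12
  # vegan cross-check (bias-corrected form is vegan's S.chao1)
  est <- vegan::estimateR(counts)
  expect_equal(chao1(counts, bias_corrected = TRUE), unname(est["S.chao1"]))
  # F2 = 0 fallback warns and uses the bias-corrected form
  c2 <- c(1, 1, 3)
  expect_warning(v <- chao1(c2), "bias-corrected")
  expect_equal(v, chao1(c2, bias_corrected = TRUE))
  # no singletons: estimate equals observed richness
  expect_equal(chao1(c(3, 4, 5)), 3)
})

test_that("shannon and pielou match the closed forms", {
  counts <- c(90, 5, 5)
  p <- counts / 100
  h <- -sum(p * log(p))
  sp <- shannon_pielou(counts)
  expect_equal(sp$shannon, h)
  expect_equal(sp$pielou, h / log(3))
  expect_equal(sp$shannon, unname(vegan::diversity(counts)))
  # equal abundances: J = 1; single OTU: H = 0, J defined as 0
  expect_equal(shannon_pielou(c(7, 7, 7, 7))$pielou, 1)
  expect_equal(shannon_pielou(42)$pielou, 0)
  expect_equal(shannon_pielou(42)$shannon, 0)
})

test_that("rarefaction matches the hypergeometric expectation", {
  # counts [2, 1], n = 2: E[S] = 2 - choose(1,2)/choose(3,2) ... = 5/3
  r <- rarefaction(c(2, 1), 2)
  expect_equal(r$expected_otus, 5 / 3)
  # brute-force oracle on a larger vector
  counts <- c(5, 3, 1, 1)
  n <- 4
  N <- sum(counts)
  exp_manual <- sum(1 - choose(N - counts, n) / choose(N, n))
  expect_equal(rarefaction(counts, n)$expected_otus, exp_manual)
  # monotone nondecreasing; endpoints
  curve <- rarefaction(counts, 1:N)
  expect_true(all(diff(curve$expected_otus) >= -1e-12))
  expect_equal(curve$expected_otus[1], 1)
  expect_equal(curve$expected_otus[N], 4)
  expect_error(rarefaction(counts, N + 1), "exceeds")
  expect_error(rarefaction(counts, 0))
})

test_that("rarefaction agrees with Monte-Carlo subsampling within 3 se", {
  set.seed(43)
  counts <- c(40, 20, 10, 5, 2, 1, 1, 1)
  pool <- rep(seq_along(counts), counts)
  n <- 25
  B <- 2000
  obs <- vapply(seq_len(B),
                function(b) length(unique(sample(pool, n))), 1L)
  mc_mean <- mean(obs)
  mc_se <- stats::sd(obs) / sqrt(B)
  expect_lt(abs(rarefaction(counts, n)$expected_otus - mc_mean), 3 * mc_se)
})

test_that("otu_counts joins reads to samples and conserves totals", {
  cl <- tibble::tibble(read_id = c("r1", "r2", "r3", "r4"),
                       otu_id = c("OTU_0001", "OTU_0001", "OTU_0002", "OTU_0002"))
  samples <- tibble::tibble(read_id = c("r1", "r2", "r3", "r4"),
                            sample_id = c("s1", "s2", "s1", "s1"))
  oc <- otu_counts(cl, samples)
  expect_identical(sum(oc$count), 4L)
  expect_identical(oc$count[oc$otu_id == "OTU_0002" & oc$sample_id == "s1"], 2L)
})

test_that("diversity_summary bundles the per-sample statistics", {
  ds <- diversity_summary(c(1, 1, 1, 1, 2, 2, 5, 5, 5, 5))
  expect_identical(ds$s_obs, 10L)
  expect_identical(ds$f1, 4L)
  expect_identical(ds$f2, 2L)
  expect_equal(ds$chao1, 14)
  expect_equal(ds$chao1_bc, 12)
})

test_that("plot_rarefaction returns a ggplot", {
  curve <- rarefaction(c(5, 3, 1), 1:5)
  expect_s3_class(plot_rarefaction(curve), "ggplot")
})
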