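---
title: "Methods behind dwbiofilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind dwbiofilm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwbiofilm)
```

This vignette records the model behind each module, the default parameter
choices and why they were made, and what the synthetic generator does and
does not emulate. The package follows the analysis shape of a combined
16S-amplicon + deep-shotgun characterization of a drinking-water biofilm:
pyrosequenced amplicons are demultiplexed, trimmed and clustered into OTUs;
Illumina pairs are filtered, dereplicated and merged into tags; an abundant
genome is binned from assembled contigs by coverage and tetranucleotide
composition and scored against single-copy markers; functional profiles of
many metagenomes are ordinated by PCA.

## Synthetic community

Since the original raw data are not available, every pipeline step is
exercised against simulated data with a planted truth.

`sim_genomes()` draws order-0 (i.i.d.) genomes with GC contents spread
evenly across `gc_range = c(0.35, 0.67)`; a warning is raised when
neighbouring genomes are closer than 0.08 GC, below which composition-based
separation becomes unreliable. Each genome carries `n_markers = 105`
single-copy marker loci placed evenly (1-based inclusive coordinates).
`marker_length = 500` bp models the conserved detectable anchor span of a
single-copy gene: loci are counted only when *fully contained* in a contig,
and 500 bp anchors make marker recovery on assembly-scale contigs match the
~95% completeness regime expected for a deeply covered, nearly complete
bin. Full-gene-sized loci would lose an additional ~8–14% of markers to
contig boundaries, which is a property of the counting rule rather than of
the bin.

`community_design()` fixes relative abundances (must sum to 1), the total
sequencing effort, the fragment length distribution
(Normal(180, 20) by default, sequenced as 100 bp pairs), and a per-base
substitution error rate (0.001). Expected fold coverage per genome is
`abundance * total_bases / genome_length`. `simulate_shotgun()` emits read
pairs plus an origin table (genome, coordinates, strand, fragment length)
used as the oracle everywhere. Qualities are Phred+33,
Normal(35, 4) clipped to [2, 40], so the Q20 quality filter has something
to act on.

`simulate_contigs()` tiles each genome end-to-end into contigs with lengths
uniform in `contig_length_range`, bypassing de novo assembly (out of
scope). Contig coverage is the genome's expected fold coverage times
multiplicative lognormal noise (`noise_sd` is the sdlog; 0 gives exact
coverages). Lengths below the downstream 300 bp filter are produced on
purpose so the filter is exercised.

`simulate_amplicons()` emits single-end reads
`barcode + forward primer + insert (+ reverse-complemented reverse
primer)`, emulating 454 amplicon libraries of a ~438 ± 16 bp region.
Degenerate primer positions are instantiated per read; substitution errors
(default 0.5% per base) apply to the insert only, treating barcode/primer
synthesis as exact.

Not emulated: pyrosequencing homopolymer errors, chimeras, indel errors,
coverage biases along the genome, assembly artefacts, and any database
annotation. These are out of scope for the workflow's logic.

## Amplicon preparation

`demultiplex()` assigns a read to the unique barcode within
`max_mismatch = 1` Hamming distance of its prefix; ties and short reads
stay unassigned, and assigned reads have the barcode removed.
`trim_primers()` honours IUPAC degeneracy and allows one mismatch per 10
primer bases (rounded up); reads without a forward-primer match are
dropped and counted. A reverse-primer *cocktail* is searched
reverse-complemented near the 3′ end, as mixtures of several reverse
primers are common in broad-range 16S PCR. `normalize_depth()` keeps the
first `n` reads per sample in file order — the simplest reproducible
depth normalization and the one used in the source workflow (n = 8,951
there); a seeded random subsample is available via `shuffle_seed`.

## Diversity

`pairwise_distance()` aligns globally with free terminal gaps
(match +1, mismatch −1, gap −2 per base) and defines distance as
mismatches / aligned columns, terminal gap columns excluded and internal
gaps counted as mismatches. Pre-aligned input is supported via
`mode = "aligned"`. `cluster_complete_linkage()` merges the closest pair
of clusters (maximum-linkage) until no merge stays at or below the
threshold; ties break deterministically on the lexicographically smallest
pair of representative ids, which is why the routine is hand-rolled rather
than delegated to `hclust`. The study thresholds are 0.03 and 0.06, and
the number of OTUs at 0.06 can never exceed that at 0.03.

Chao1 is `S_obs + F1^2 / (2 F2)` (classic) or
`S_obs + F1(F1 - 1) / (2(F2 + 1))` (bias-corrected); when the classic form
is requested with `F2 = 0 < F1` the bias-corrected form is used with a
warning. Shannon uses the natural log (and Pielou `J = H / ln S`, with
`J = 0` for a single OTU). Rarefaction is the exact hypergeometric
expectation `E[S(n)] = Σ (1 − C(N−N_i, n)/C(N, n))`, evaluated through
`vegan::rarefy`.

## Taxonomy

`tax_train()` implements the RDP-style naive Bayes prior: for word size
`k = 8`, genus *g* with *M* training sequences of which *m(w)* contain word
*w*, `P(w|g) = (m(w) + 0.5) / (M + 1)`. `tax_classify()` scores each
read's *distinct* words on both strands, keeps the better orientation,
and estimates confidence from 100 bootstrap trials of ⌈W/8⌉ words each;
the per-rank confidence is the fraction of trial winners sharing the best
genus's taxon at that rank, thresholded at 0.8 downstream
(`summarize_ranks()`, which uses domain-assigned reads as the 100% base).

Two training regimes matter:

- **Reference-database regime** (what RDP actually does): training
  sequences are short (a 16S gene is ~1.5 kb), so 8-mer presence is sparse
  and a read shares its exact words with its own genus's reference and
  essentially no other. This is the regime of the package's
  self-consistency guarantee (≥ 99% accuracy at ≥ 0.8 confidence).
- **Whole-genome regime**: on Mb-scale i.i.d. genomes every 8-mer is
  present in every genome (~9–15 expected copies per Mb), so presence
  carries no identity signal. `as_training_refs()` therefore splits each
  genome into `fragments_per_genome = 25` training sequences, which turns
  the prior into an informative word-frequency (composition) estimate —
  but accuracy is then limited by the GC separation of the genomes, not by
  the classifier.

## Shotgun preparation

`quality_filter()` discards a read iff its N fraction exceeds 10% **or**
its fraction of bases below Q20 exceeds 50%; both comparisons are strict,
so a 100 bp read with exactly 10 N or exactly 50 bases at Q19 survives.
For pairs, either failing mate discards the pair. `dereplicate()`
collapses reads whose first 50 bp (of the forward mate, by default) are
identical, keeping the first occurrence — the standard treatment of
Illumina PCR duplicates. `merge_tags()` reverse-complements the reverse
mate and evaluates every substitution-only overlap of ≥ 10 bp; among
overlaps with ≤ 10% mismatches the one with the most matching bases wins,
ties go to the longer overlap, and a still-tied pair is left unmerged as
ambiguous. Consensus takes the higher-quality base at disagreements and
the larger quality at agreements. Error-free pairs from ~Normal(159, 9)
fragments yield tags centred on 159 bp, the tag-length scale of the
source data.

## Binning and bin QC

Contigs ≥ 300 bp with mean coverage inside the inclusive 300–600× window
are candidates (`select_by_coverage()`); the study's target genome sat in
an obvious ~450× coverage cluster. `tnf()` computes canonical
tetranucleotide frequencies: the 256 tetramers fold into 136 classes (120
reverse-complement pairs + 16 palindromes) via `min(w, revcomp(w))`, making
the vector strand-independent. `tnf_filter()` removes composition
outliers: a robust centroid (length-weighted component-wise median) is
computed, contigs within the 95th percentile of Euclidean TNF distance are
kept, and one refinement pass re-derives both the centroid and the
retention threshold from the kept set before re-screening all candidates —
so contamination cannot inflate the cut-off. A k-means alternative
(k chosen by mean silhouette width, largest cluster by bp kept) is
provided since the original binning tool's internals are not documented.
Note the percentile rule intentionally trims ~`(q/100)^2` of even a pure
candidate set by count (~5% by bp, short-contig-dominated).

`score_bin()` reports completeness (fraction of the single-copy marker set
present) and redundancy (fraction of present markers in > 1 copy); 100 of
105 markers once each gives 95.24% / 0%. `estimate_abundance()` computes
`100 * mean_coverage * (bin_bp / completeness) / total_sequenced_bp`
(dividing by completeness extrapolates the bin to the full genome size);
it is invariant under jointly scaling coverage and total depth.

## Functional profiles and PCA

`normalize_profiles()` scales each sample's counts to relative abundances
(the percentage-of-annotated-reads convention); optional column
z-standardization drops zero-variance categories with a warning.
`profile_pca()` is covariance PCA via singular values (`prcomp`);
correlation PCA is available with `scale = TRUE`. Covariance on relative
abundances is the default because the upstream normalization already puts
categories on a common scale. Loading signs follow the convention that
each loading vector's largest-magnitude entry is positive, making results
reproducible across platforms. `tidy()`/`glance()`/`autoplot()` methods
expose scores, loadings, eigenvalues and the PC1 × PC2 ordination.

## Decisions on under-specified points

- "First N reads" means file order; random subsampling is opt-in and
  seeded.
- The contig length filter is ≥ 300 bp by default (`strict_len = TRUE`
  for > 300), and the coverage window is inclusive at both ends.
- Dereplication keys on the forward mate's first 50 bp
  (`both_mates = TRUE` to key on both).
- Both Chao1 variants are exposed; the classic form is the default, with
  the documented fallback when `F2 = 0`.
- Shannon uses the natural log; `base` is a parameter.
- Acceptance-scale problem sizes: 5 genomes of 0.5–1 Mb for binning (one
  planted at 28% abundance / 450×, coverage noise sdlog 0.05 so the
  coverage window is a faithful selector), 2 kb reference sequences with
  150 bp reads for classifier self-consistency, ≤ 12 reads for the
  exhaustive clustering oracle, and ~400 error-free pairs for the
  tag-length statistics.

## Worked pipeline

```{r, eval = FALSE}
comm <- sim_binning_community(seed = 7)
ctg  <- simulate_contigs(comm$genomes, comm$design, noise_sd = 0.05, seed = 8)
bin  <- tnf_filter(select_by_coverage(ctg))
sc   <- score_bin(emit_marker_hits(bin, comm$genomes), marker_set(105))
estimate_abundance(bin, completeness = sc$completeness / 100,
                   total_sequenced_bp = comm$design$total_bases)
```
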