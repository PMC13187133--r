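---
title: "Methods: curation, diversity and metaphylogeography of port COI metabarcoding data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, diversity and metaphylogeography of port COI metabarcoding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaport)
```

## Data model

`metaport` works on three linked containers:

* a `sample_frame`: one row per sequencing sample, with locality, time point,
  replicate, and a sample type in `{true_sample, blank, pcr_negative}`;
* an `esv_table`: a reads matrix of exact sequence variants (ESVs, used as a
  haplotype proxy) by samples, each ESV linked to a parent MOTU and
  optionally carrying its nucleotide sequence;
* a `motu_table`: the MOTU-by-sample reads matrix (MOTUs are the species
  proxy), with a ranked taxonomy string, an optional nominal species, and a
  dataset label in `{NIS, NAT, COMM_other, excluded}`.

The invariant connecting the two read tables — each MOTU's reads equal the sum
of its ESVs' reads per sample — is checked by `validate_linkage()` and
re-established by `rebuild_motu_table()` after every ESV-level filter.
MOTU-level analyses (alpha and beta diversity) and ESV-level analyses
(haplotype richness, differentiation) therefore always see mutually consistent
tables.

Three dataset scopes recur throughout: **NIS** (MOTUs matched to a curated
non-indigenous reference), **NAT** (the curated native subset), and **COMM**
(the whole community minus NIS).

## Filtering cascade

The cascade in `run_filter_cascade()` applies, in order:

1. **Blank filter.** An ESV is deleted when its reads in control samples
   (blanks plus PCR negatives) exceed `blank_fraction_threshold` (default
   0.10) of its reads in true samples. The inequality is strict: an ESV at
   exactly 10% is retained. The denominator is the true-sample reads by
   default (`blank_denominator = "true_samples"`); totals over all samples are
   available as an option.
2. **Dual abundance filter**, per sample and in a fixed order: (i) cells
   below `rel_abundance_threshold` (default 0.005%) of the sample's
   *pre-filter* total are zeroed; (ii) cells below `min_reads_per_esv_sample`
   (default 5) reads are zeroed, evaluated on the values left by step (i).
   Both comparisons are strict ("less than"), so 5-read cells at a
   sufficiently deep sample survive while 4-read cells do not. The order is
   part of the definition: swapping the steps and recomputing the relative
   floor on the reduced totals changes the output (the test suite pins this
   with a crafted example).
3. **Pseudogene filter.** Each sequence is translated in the configured frame
   (default offset 2, matching the Leray COI fragment, whose 313 bp comprise
   2 leading bases, 103 codons, and 2 trailing bases) under every configured
   genetic code (default: the eight metazoan mitochondrial code tables
   available in `Biostrings`: 2, 4, 5, 9, 13, 14, 21, 24). An ESV is deleted
   only when a stop codon appears under *every* code — a conservative rule
   that avoids discarding genuine COI from taxa using an unusual code. An
   optional conserved-residue check (`conserved_positions`) can additionally
   require specific amino acids at specific positions of the stop-free
   translation; it is empty by default because the appropriate profile
   depends on the amplicon and taxonomic scope.
4. **Metazoan restriction** by phylum (configurable list or predicate).
5. **Sample-depth filter.** True samples with fewer than `min_sample_depth`
   reads (default 9500) are discarded (strict inequality), and ESVs emptied
   by the removal are dropped.

Every deletion is recorded in a removal log (`esv_id`, stage, reason, reads
removed) written alongside the filtered tables.

## NIS classification and dataset partition

`assign_nis()` labels a MOTU non-indigenous when any hit against the curated
reference reaches **at least** 97% identity **and** 70% coverage (both
boundaries inclusive). The nominal species comes from the best hit, with ties
broken by identity, then coverage, then lexicographic species name, making the
result invariant to the order of hit rows. `curate_nat()` defines the native
subset: species-level-assigned non-NIS MOTUs minus an explicit exclusion list
(species complexes, dubious matches, cryptogenic species), which may be given
as MOTU ids or binomials. `partition_datasets()` enforces that NIS and NAT are
disjoint and labels the remainder `COMM_other`.

## Alpha and beta diversity

Alpha diversity is computed per sample at a common depth (the shallowest
sample by default). Richness uses the analytic hypergeometric expectation
(`vegan::rarefy`); Shannon diversity (natural log) is computed on a seeded
without-replacement draw (`vegan::rrarefy`), optionally averaged over several
draws. Localities are compared with ANOVA plus Tukey HSD for Shannon and
Kruskal–Wallis plus a tie-corrected Dunn test for richness — the rank-based
route because rarefied richness is bounded and typically non-normal.

Beta diversity uses Bray–Curtis dissimilarity on per-sample relative
abundances (no rarefaction: relative abundances remove depth as a first-order
effect while retaining all taxa). Sørensen similarity between localities is
computed by default on locality-pooled incidence — the natural scale for
"how much of the regional pool do two ports share" — with a sample-pair
average available as an option. Location effects are tested with a one-way
PERMANOVA (Anderson's pseudo-F on squared dissimilarities; permutation
p-values use the (hits + 1)/(n_perm + 1) convention, with exhaustive
enumeration available for n ≤ 8), cross-checked in the test suite against
`vegan::adonis2`. Dispersion differences use distances to group centroids in
principal-coordinate space (`vegan::betadisper`) with a permutation F test.
Temporal turnover is the mean Bray–Curtis between consecutive months within
each locality, averaged over localities.

## Metaphylogeography

The intraspecific level treats each MOTU as a population of ESVs.

**ESV richness.** `esv_richness_summary()` counts nonzero ESVs per MOTU;
NIS and NAT are compared with a two-sided Mann–Whitney test (normal
approximation, since counts are heavily tied). Because NIS are also more
read-abundant and ESV counts grow with reads, two confound controls are
provided: (a) `rarefy_motu_reads()` subsamples every MOTU's reads without
replacement to a common threshold (the mean or median NAT total, or an
explicit value) using sequential hypergeometric draws over its (ESV, sample)
cells — totals hit the threshold exactly and per-sample proportions are
preserved in expectation — after which the richness test is rerun; and (b)
`randomization_balance_test()` repeatedly subsamples the larger group to the
smaller group's size. The reads–richness relationship itself is summarised by
per-dataset log–log regressions with a slope-homogeneity test via the
interaction term of the joint model.

**Differentiation.** For a MOTU and a locality pair, the abundance proxy is
the *occurrence count*: for each ESV, the number of samples per locality with
at least one read. Occurrences are more robust than read counts to PCR and
sequencing abundance distortions. Jost's D is estimated with the
Nei–Chesser-style bias correction: with column totals \(N_j\), frequencies
\(p_{ij} = x_{ij}/N_j\), harmonic mean \(\tilde n\) of the \(N_j\), and
\(n = 2\) subpopulations,

\[ H_s = \tfrac1n \sum_j (1 - \sum_i p_{ij}^2), \qquad
   \hat H_s = \tfrac{\tilde n}{\tilde n - 1} H_s, \]
\[ H_t = 1 - \sum_i \bar p_i^2, \qquad
   \hat H_t = H_t + \tfrac{\hat H_s}{n \tilde n}, \qquad
   D = \tfrac{n}{n-1} \cdot \tfrac{\hat H_t - \hat H_s}{1 - \hat H_s}. \]

Negative estimates (sampling noise around zero differentiation) are clamped
to zero after estimation. The estimator is undefined when both localities
carry a single occurrence (\(\tilde n = 1\)); this raises an error rather
than returning a silent value. Per locality pair, eligible MOTUs are those
present in both localities with at least two ESVs showing nonzero occurrence
pooled over the pair (a stricter per-locality eligibility is available);
`mean_d_between_localities()` averages the per-MOTU D values, and
`compare_jost_d()` contrasts NIS against NAT across the same locality pairs
with a paired t-test and Pearson correlation.

## Synthetic data generator

`simulate_dataset()` exists so that every stage is testable without
sequencing data. Its model, with defaults chosen to resemble a multi-port
monitoring campaign while staying cheap to simulate:

* **Design.** 4 localities × 10 monthly time points × 3 replicates, plus 2
  blanks and 2 PCR negatives (all configurable). These sizes are this
  package's own choice of a representative problem size; a full run stays
  under a minute on one CPU.
* **MOTU classes.** 25 NIS, 60 NAT, 90 other, 5 non-metazoan. Per-MOTU
  abundance weights are lognormal with an 8× multiplier for NIS
  (read-abundant invaders); occupancy per locality is Bernoulli with
  probability 0.8 for NIS (widespread) versus 0.3 for natives
  (locality-restricted); a lognormal month effect (sd 0.4) creates temporal
  structure.
* **Haplotypes.** ESV counts per MOTU are zero-truncated negative binomial
  (mean 9 for NIS vs 3 for others, dispersion 2). Haplotype frequencies per
  locality mix a shared Dirichlet(1) base vector with a locality-private
  Dirichlet(0.3) vector with weight `theta` (0 = identical frequencies
  everywhere, 1 = fully private); defaults 0.15 for NIS vs 0.35 for natives
  encode weaker between-port differentiation of invaders. `theta` is the
  generator's key recoverable parameter: the acceptance tests check mean D is
  ~0 at `theta = 0` and increases monotonically in `theta`.
* **Reads.** Per true sample, a multinomial draw at lognormal depth
  (median 30,000, sdlog 0.35) with cell probabilities proportional to MOTU
  weight × occupancy × month effect × haplotype frequency.
* **Sequences.** 313 bp fragments with the Leray geometry whose in-frame
  codons come from the set that is stop-free under all checked genetic
  codes; variants differ at third codon positions. Pseudogene spike-ins
  carry an in-frame TAG (a stop under every metazoan mitochondrial code);
  contaminant spike-ins concentrate their reads in control samples. Both are
  injected at 2% of the clean ESV count, so filter recovery is measurable
  exactly against the ground-truth ledger in `$truth`.
* **Reference hits.** Every NIS MOTU receives a qualifying hit
  (identity 97.5–100, coverage 75–100); decoy hits below the identity
  threshold are attached to a random tenth of the other MOTUs.

`worked_fixture()` complements the generator with a fixed 13-ESV bundle where
every filter boundary (10% blank share, 0.005%/5-read dual filter, depth
threshold) has one offender and one survivor placed exactly at the boundary,
and the one shared polymorphic MOTU has occurrence counts (3,1)/(1,3) giving
D = 0.25 by hand.

## Numerical choices

* Read matrices are stored as doubles to avoid integer overflow in totals.
* All "more than"/"less than" thresholds are strict inequalities; boundary
  cases are pinned by fixtures in the test suite.
* Permutation p-values use the add-one convention, so the smallest attainable
  p with 999 permutations is 1/1000; exhaustive enumeration replaces sampling
  for n ≤ 8.
* Per-stage seeds are derived deterministically from the master seed, so
  pipeline runs are exactly reproducible (byte-identical JSON reports).
* Translation is vectorised over all sequences per genetic code (8 calls to
  `Biostrings::translate` rather than one per ESV), keeping the pseudogene
  filter linear in practice.
* Jost's D is computed in plain arithmetic from the occurrence matrix; the
  test suite checks it against a literal re-transcription of the estimator
  and against brute-force enumeration of all small matrices.

## Limitations

* The generator draws haplotype frequencies independently per locality given
  the shared base vector; it has no explicit migration model, spatial
  autocorrelation between ports, or seasonality beyond the lognormal month
  effect. It supports recovery tests of orderings and of `theta`, not
  quantitative fits of any particular empirical dataset.
* PERMANOVA is one-way; crossed or nested designs (locality × season) must be
  tested one factor at a time.
* The pseudogene filter's conserved-residue check defaults to off; supplying
  a profile appropriate to the amplicon is the user's responsibility.
* Occurrence counts saturate when an ESV is present in every sample of a
  locality, compressing D toward zero in very well-sampled designs.
* NIS classification trusts the curated reference: misidentified or missing
  reference sequences propagate directly into the NIS set.
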