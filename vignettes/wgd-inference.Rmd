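---
title: "Inferring whole-genome duplications from paralog divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring whole-genome duplications from paralog divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdtrace)
```

## The problem

Ancient polyploidization (whole-genome duplication, WGD) leaves two
complementary footprints in a modern genome. First, paralogous gene
pairs created at the same event share a common divergence time, so a
neutral divergence statistic computed over many pairs piles up into
waves — one wave per event. Second, the duplicated genes sit in
collinear blocks ("paralogons") spread across chromosomes, a pattern
tandem duplication plus translocation cannot easily forge. `wgdtrace`
implements the full desk pipeline for both lines of evidence, in the
form used to argue for three WGD rounds in horseshoe crabs: paralog
family construction by Markov clustering, the corrected 4DTv statistic,
normal-mixture dating of the waves, tandem-array detection, collinear
anchor chaining, plus the k-mer genome-size estimate and contig
curation rules that precede annotation-level work.

Because the original data (a multi-gigabase assembly and hundreds of
gigabases of reads) are not reproducible at desk scale, every stage is
paired with a simulator that generates data with *known* duplication
truth, and the test suite measures recovery of that truth.

## The 4DTv statistic

A four-fold degenerate (4D) site is the third position of a codon whose
first two bases fix the amino acid regardless of the third (the eight
codon families CTN, GTN, TCN, CCN, ACN, GCN, CGN, GGN). Between two
aligned coding sequences, the raw statistic is

> 4DTv = (number of transversion differences at shared 4D sites) / (number of shared 4D sites),

where a transversion pairs a purine (A, G) with a pyrimidine (C, T).
Because repeated substitutions saturate the raw proportion at 0.5, it
is corrected for multiple hits:

> 4DTv~corrected~ = −½ · ln(1 − 2 · 4DTv).

Under a two-parameter substitution process with transition rate α and
per-target transversion rate β, purine/pyrimidine identity is a
two-state chain with flip rate 2β, so a pair separated for total time
T differs by a transversion with probability Q = (1 − e^(−4βT))/2 and
the corrected statistic is an unbiased estimator of the transversion
distance 2βT. This is the depth scale used throughout: a "depth 0.85"
event means pairs born there have expected corrected 4DTv 0.85.
`extract_4d_sites()` requires the two codons of a column to share the
same first two bases before accepting the site — a prefix change can
move the codon out of its degeneracy class, so the conservative rule
avoids miscounting. Pairs need at least 30 shared 4D sites to pass the
filter (`min_sites`), and pairs with raw 4DTv at or above 0.5 are
flagged saturated and excluded from mixture input, because the
logarithm is undefined there.

## From proteins to paralog families

`all_vs_all_similarity()` either ingests a precomputed BLAST 12-column
table or aligns the proteins itself (BLOSUM62, affine gaps 11/1, exact
dynamic programming) at synthetic scale. The built-in engine
deduplicates identical sequences, seeds candidate pairs on shared
8-residue words (at least two), and converts scores to E-values with
gapped Karlin–Altschul parameters (λ = 0.267, K = 0.041) against the
summed database length. E-values are kept in log10 throughout: deeply
similar protein pairs reach E-values far below the smallest positive
double, and the MCL edge weight (−log10 E, capped at 200) must survive
that. The 8-residue word length is deliberate: amino-acid frequencies
under uniform codon usage are skewed enough that unrelated 2,000-residue
proteins share 6-mers by chance quite often, while chance 8-mer sharing
is negligible.

`mcl_cluster()` is a from-scratch Markov Cluster implementation:
self-loops set to each node's maximum incident weight, column-stochastic
normalisation, then alternating expansion (matrix squaring) and
inflation (entrywise power, default 6, then renormalisation) with
pruning below `tol`, run independently per connected component.
Clusters are the merged supports of the attractor rows. Inflation 6
gives fine-grained families appropriate for separating paralog families
rather than superfamilies. Families are then filtered to 2–8 members
(`filter_family_sizes()`); up to 8 members is exactly what three rounds
of WGD can produce from one ancestral gene, and the synteny variant
keeps singletons with `min_size = 1`.

One subtlety is worth recording. For the weighted path a—b—c with
w(ab) = 1 and w(bc) = 0.01 at inflation 6, a high-precision fixed-point
iteration of the expansion/inflation recurrence under the max-incident
self-loop policy converges to a single attractor covering all three
nodes, i.e. one cluster {a, b, c}; splitting {a, b} from {c} requires
unit self-loops instead. The package keeps the max-incident policy (a
standard MCL regularisation) and the tests freeze the oracle-computed
fixed point, not an assumed answer.

## Mixture dating of duplication waves

The corrected 4DTv values of all retained pairs are fitted with
univariate normal mixtures by expectation-maximisation
(`fit_normal_mixture()`, compiled core), in both equal- and
unequal-variance families, for k = 1..8 components;
`select_model_bic()` picks the minimum of BIC = −2·loglik + p·ln n,
with ties toward fewer components and equal variance. Component
standard deviations are floored at 1e-4 so no component can collapse
onto a single observation. Starts are k-means++-seeded; each restart
runs a short burn-in and only the best start is run to convergence, the
usual multi-start economy. `fit_normal_mixture()` defaults to 20
restarts at tolerance 1e-7; `select_model_bic()` screens with 5
restarts at 1e-5, which is the operating point of standard mixture
selectors, and the winner can be refit tightly if needed.

`classify_wgd_peaks()` labels components with mean below 0.1 as
small-scale-duplication (SSD) peaks — recent tandem and proximal
duplicates have corrected 4DTv near zero — and the remainder as WGD
peaks, in ascending order. The 0.1 boundary is configurable; it sits
comfortably between an SSD peak near 0.02 and a first WGD wave near
0.4.

### What BIC can and cannot recover here

When each wave really is Gaussian, selection is reliable: the test
suite draws three waves at means 0.40/0.85/1.33 (sds 0.07/0.10/0.15,
n = 10,000) and BIC recovers k = 3 with means within ±0.03, and k = 1
on single-wave controls. The end-to-end simulation is harder in an
instructive way: with every pair of a wave evolved for exactly the same
time, the raw 4DTv of the oldest wave is a Binomial(n_sites, 0.466)
proportion, and the log-transform that defines the corrected scale maps
its sampling distribution to a strongly right-skewed one. Given a few
thousand pairs, BIC correctly concludes that one Gaussian per wave does
not fit that skew and spends extra components on it — mclust, run on
identical draws, does the same. The acceptance suite therefore measures
and reports the whole-pipeline three-wave recovery rate honestly rather
than arranging conditions to mask the effect. On real data the same
caution applies in reverse: the number of BIC components is an upper
bound on the number of WGD events, and wave identities should be
confirmed against synteny evidence.

## Tandem gene clusters

`find_tandem_clusters()` applies three rules per chromosome and gene
name: same-name genes are chained while consecutive occurrences are
separated by at most 5 unrelated (different-name) genes; within a
chain, a copy is kept only if its global protein identity to at least
one other kept copy is at least 70% (single-linkage, which tolerates
gradient divergence across an array); chains with at least 3 survivors
become clusters. Genes without names never match. Because dropping an
identity-isolated copy can widen a gap past the bound, chaining and
filtering are iterated to a fixed point; the result then matches a
brute-force enumeration of maximal subsets satisfying both rules, which
the tests run on random annotations. `confirm_against_reference()`
assigns each member its best-scoring reference protein and flags a
cluster confirmed when a strict majority agrees — tandem copies of a
real array typically hit the same reference.

## Paralogons

`build_anchor_pairs()` collapses tandem members of each family to one
representative (longest protein, ties to the smaller rank, groups
joined transitively at ≤ 5 intervening genes) and emits every
representative pair as an anchor. `chain_collinear_blocks()` extracts,
per chromosome pair and orientation, strictly monotone anchor chains
with per-step rank gaps of at most 25 genes on both sides, greedily by
decreasing chain length (the per-pair chain search itself is an exact
dynamic program); blocks need at least 3 anchors. Intra-chromosomal
blocks are allowed — chromosome fusions after WGD produce them — but
the two sides must be at least 25 ranks apart so a block cannot pair a
region with itself. This chaining is a deliberately simplified,
deterministic stand-in for probabilistic collinearity tools;
`paralogon_summary()` produces the per-chromosome anchor totals and the
symmetric shared-anchor matrix that a circos-style figure displays.

## Genome size from k-mer spectra

A diploid short-read k-mer copy-number (KCN) spectrum shows an error
spike at low KCN, a heterozygous mode at the k-mer coverage c/2 and a
homozygous mode at c. `detect_kcn_peaks()` smooths the spectrum with a
centered 5-wide moving average (raw low-KCN counts are noisy; the
window is the smallest that stabilises the first minimum), takes the
first KCN where smoothed counts stop decreasing as the error cutoff,
and calls modes above it. The two tallest modes are accepted as a
het/hom pair only when their KCN ratio lies in [1.7, 2.3] *and* the
smaller is at least 20% of the taller's height — the height floor stops
sparse tail ripples from impersonating a homozygous peak. Genome size
is Lander–Waterman on k-mer instances:
(Σ kcn·count − Σ_{kcn ≤ error cutoff} kcn·count) / hom_peak.
The division uses k-mer coverage units directly; the read-coverage
conversion hom_peak·L/(L−k+1) is reported for information when the
read length is supplied, because the two conventions differ by a known
factor and the instance formulation is the self-consistent, testable
one.

## Contig curation

`remove_duplicate_contigs()` removes a contig when an alignment against
a larger surviving contig reaches ≥ 95% identity (matches / aligned
columns) over ≥ 80% of the smaller contig's length; removals cascade
against survivors only, and equal-length exact ties drop the
lexicographically later id for determinism.
`merge_terminal_overlaps()` joins contigs whose suffix/prefix overlap
exceeds 30 kb at ≥ 95% identity (both orientations checked; the
overlap must be strictly terminal on both contigs), keeping the first
contig's bases across the join. Passes repeat until no merge applies,
so chains collapse fully and the operation is idempotent. Alignment is
exact affine-gap dynamic programming with a shared-k-mer prescreen that
only skips pairs far below any threshold of interest. Thresholds are
arguments, so tests run the same rules on kilobase-scale contigs with
a 3 kb overlap bound.

## The simulators

`simulate_wgd_genome()` is the package's ground-truth machine. All
genes are random stop-free CDSs of `cds_length_codons` codons
(default 2,000, putting a typical pair around a thousand shared 4D
sites — the precision regime the calibration properties are stated
at). Each WGD event copies every surviving gene onto a duplicated
chromosome and keeps each new duplicate independently with
`retention_prob`; between events only 4D third positions evolve, under
the two-parameter process with κ = 2, with branch durations set so
that a pair split at depth d has expected corrected 4DTv exactly d.
Everything else — nonsynonymous sites, codon prefixes — is frozen, so
proteins stay identical within a family and alignment is exact by
construction: tests of the 4DTv stage isolate the statistic, never the
aligner. Tandem arrays are inserted as adjacent same-name copies with a
controlled protein identity (disjoint nonsynonymous mutations, so
pairwise identity is exact) and synonymous divergence zero, making
them both tandem-detection truth and an SSD peak at depth 0. Decoy
singletons add unrelated background. The simulator does not model
introns, indels, rate variation among pairs, recombination or
read-level sequencing — so passing tests demonstrate correctness of
the statistics and algorithms under the stated model, not robustness
to alignment error or rate heterogeneity in real annotations.

`simulate_kmer_histogram()` draws per-locus depths from Poisson
distributions (hom at c, two half-depth variants per heterozygous
locus, error k-mers decaying geometrically from KCN 1);
`simulate_contig_set()` cuts a random genome into fragments with known
terminal overlaps and appends noisy duplicates, recording exactly which
contigs curation should remove or merge. All simulators are
bit-reproducible under their seed.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_wgd_genome(wgd_sim_config(
  n_ancestral_genes = 100, wgd_depths = c(1.33, 0.85, 0.4),
  retention_prob = 0.8, cds_length_codons = 600, seed = 7))

proteins <- setNames(sim$genes$protein, sim$genes$gene_id)
families <- all_vs_all_similarity(proteins) %>%
  mcl_cluster(all_ids = names(proteins)) %>%
  filter_family_sizes()

records <- fourdtv_families(families, sim$genes)
values <- records$fourdtv_corrected[records$passes_filter]
model <- select_model_bic(values, seed = 7)
classify_wgd_peaks(model)
autoplot(model, values)
```

## Numerical choices and limitations

* Internal coordinates are 0-based half-open; conversion happens only
  at format boundaries, so span arithmetic and intervening-gene counts
  never carry off-by-one risk.
* Gene names are read from GFF3 attributes in priority
  `Name` > `description` > `product`, falling back to the gene id.
* BLAST HSP collapsing keeps the single best-bitscore HSP per ordered
  pair rather than merging HSPs — the simplest deterministic contract.
* The EM tolerance is relative to the log-likelihood magnitude;
  monotonicity of the trace is asserted in tests.
* Greedy block extraction is exact when optimal chains are disjoint
  (asserted against exhaustive search on such cases) and can in
  principle split interleaved chains suboptimally.
* Karlin–Altschul parameters are fixed constants; E-values at
  synthetic scale are meant for thresholding, not for agreement with
  any particular BLAST build.
* Saturated 4DTv pairs are reported but never fed to the mixture;
  heavily saturated data (oldest events near the 0.5 raw bound)
  therefore lose pairs, and the oldest wave's weight is a lower bound.
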