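---
title: "Molecular count estimation in dropcount: models, assumptions and design choices"
author: "dropcount authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular count estimation in dropcount}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropcount)
```

Droplet single-cell RNA-seq estimates the expression of a gene in a cell as
the number of distinct unique molecular identifiers (UMIs) observed for that
gene in that cell. Three technical processes distort this count, and a
fourth question — whether a barcode corresponds to an intact cell at all —
decides which counts should be reported. dropcount implements one
correction for each distortion plus a cell-quality classifier, together
with a synthetic droplet generator that provides ground truth for all of
them. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic tests do and do not demonstrate.

## UMI collisions

When a gene produces $n$ molecules and the UMI pool has $m$ sequences, two
molecules can draw the same UMI and the observed number of distinct UMIs
$k$ under-reports $n$. Under a uniform pool the expected count follows
$k = m(1 - e^{-n/m})$, inverted in closed form as $n = -m\ln(1 - k/m)$
(`collisions_uniform()`). Real droplet libraries, however, use the pool
very unevenly — a small set of (often low-complexity) sequences carries a
disproportionate share of molecules — which makes collisions considerably
more frequent than the uniform formula predicts.

`build_collision_table()` therefore models the collision process under the
*empirical* distribution $p(u)$ estimated from all molecules
(`estimate_umi_distribution()`). With $n(k)$ molecules already drawn, the
probability that one more molecule shows a new UMI is
$p(\mathrm{new}) = \sum_i p(u_i)\,(1 - p(u_i))^{n(k)}$, and each further
distinct UMI costs $1/p(\mathrm{new})$ draws in expectation:
$n(k+1) = n(k) + p(\mathrm{new})^{-1}$, starting from $n(1) = 1$.

Two numerical points are worth recording:

* The stepwise recursion tracks the *exact* expectation of the sampling
  process. For a uniform pool the exact expectation is the partial harmonic
  sum $\sum_{i<k} m/(m-i)$, which the closed form $-m\ln(1-k/m)$
  approximates from above; near $k = 0.9\,m$ the closed form overshoots the
  exact value by about 3% at $m = 64$ and 1.3% at $m = 256$, shrinking to
  under 0.1% at $m = 4096$. The package follows the stepwise process (the
  bootstrap oracle in the test suite confirms agreement with direct
  simulation to within its 99% confidence interval); agreement with the
  closed form is correspondingly loose at small pools. This is a property
  of the two formulas, not an implementation artifact.
* Only observed sequences carry probability mass in the empirical model;
  the uniform comparator keeps the nominal pool $4^L$. When
  $\max(k)/m$ is below a configurable threshold (default 0.01) the
  adjustment is skipped — it is numerically irrelevant there.

## UMI sequence errors

A single-base error in a UMI creates a spurious molecule at Hamming
distance 1 from its parent. Within each cell–gene group, for every target
UMI $U$ (processed in descending read order) the package examines its
adjacent UMIs, split into the small side $N_S$ (reads $\le R$, ties
included) and the large side $N_L$. The posterior over "how many of the
small-side neighbours are error copies of $U$" multiplies four terms:

1. **Quality likelihoods.** The mean Phred score of each neighbour at the
   distinguishing position enters through quantized distributions $p(q)$
   and $p(q \mid \mathrm{Err})$. Both are trained without external labels:
   genes carrying exactly two adjacent UMIs almost certainly contain one
   error pair, so the smaller member supplies the error sample. Qualities
   are quantized to at most `k_quantiles` (default 15) support points;
   quantiles closer than $10^{-5}$ are merged. A small pseudocount (0.5)
   regularizes $p(q \mid \mathrm{Err})$ so that no quality value has
   exactly zero error mass — without it a single unusual training set
   could make whole quality strata unremovable.
2. **A prior on real adjacent UMIs.** Drawing $S_g - 1$ other molecules
   from the pool, the number $N'$ of distinct *real* neighbours of $U$
   follows a Markov chain: from state $k$, a draw lands on a new adjacent
   sequence with probability $p_{\mathrm{adj}}(K-k)/K$, where $K = 3L$ and
   $p_{\mathrm{adj}}$ is the pool mass adjacent to $U$. The chain is
   tabulated by dynamic programming, cached per quantized
   $p_{\mathrm{adj}}$ (step `dp_step`, default 0.01), and sliced at
   $N' = n + N_L$ to give the real-count prior.
3. **An error-count model.** Erroneous reads arise at a constant per-read
   rate $p_E$, estimated on the same training pairs as
   $\sum r / \sum (r + R)$; the total erroneous read count is modelled
   binomially with the cumulative reads of the candidate prefix.
4. **Collision correction among errors.** Several error events can hit the
   same sequence; the same dynamic program with adjacency mass 1 converts
   total error events into distinct observed error UMIs.

The exhaustive search over subsets of the neighbourhood is $O(2^{|\Omega|})$,
but error probability decays exponentially in read count, so candidates
are ordered most-error-like first (ascending reads, then descending
quality likelihood ratio, ties broken by sequence) and only the nested
prefixes of that order are scored — $O(|\Omega|)$ evaluations. The test
suite verifies that the incremental computation reproduces direct
evaluation of each nested split to $10^{-9}$.

Deletion uses the MAP error count; removed UMIs hand their reads to the
target so reads are conserved (configurable semantics were considered;
conservation was chosen because it keeps every downstream total
interpretable). The procedure iterates per group until a full pass deletes
nothing, with a cap of `max_iterations = 10`; convergence in one or two
passes is typical and the cap exists only as a guard, with a warning when
it is hit.

The baselines — cluster (drop a UMI when an adjacent UMI has at least as
many reads; *cluster-neq* requires strictly more), and directional (drop
when an adjacent UMI has more than twice the reads, absorbing
transitively along the network) — are implemented for comparison. For
cluster's read-count ties the lexicographically smaller UMI wins; the rule
must be deterministic and the -neq variant exists precisely to avoid the
case.

## Cellular barcode errors

A barcode sequencing error reroutes part of a cell's reads to a child
barcode. Because molecules carry more than one read on average, the child
inherits *exact* gene–UMI pairs from the parent — far more compositional
overlap than two independent cells produce. For a candidate pair, the
observed intersection $C$ (summed UMI-set intersections over shared genes)
is compared with its expectation under independence,
$EC = \sum_u (1-(1-p(u))^{S_i'})(1-(1-p(u))^{S_j'})$ per shared gene, with
gene sizes mapped through the collision table ($S' \ge S$). $C$ is tested
against Poisson($EC$); the p value is the upper tail. Each barcode is
compared against larger barcodes within Hamming distance 2 (configurable);
p values are Bonferroni-adjusted over the candidate count per source, and
the source merges into the candidate with the smallest adjusted p value
below `cb_alpha` (default 0.01 — the test significance level is not a
published constant, so the package treats it as a tunable). Merging is
one-pass, smallest source first, and a barcode that has received a merge
is never merged away — the plan is a one-level forest, which keeps
application order-independent and makes conservation trivial to verify.

The simple baseline merges every barcode into its largest within-distance
neighbour; the known-barcode method reassigns non-whitelist barcodes to
the nearest valid barcode holding at least as many molecules, with
equidistant ties resolved by the composition test when a UMI distribution
is available. On two-species synthetic data the audit counts merges whose
source and target are assigned to different organisms — a direct readout
of false merges.

## Damaged and low-quality cells

True quality labels do not exist, so training labels come from the barcode
rank curve: on $\log(\text{size})$ vs $\log(\text{rank})$ the canonical
curve has a concave head, a linear middle and a convex tail.
`size_thresholds()` fits a stiff smoothing spline (default 6 degrees of
freedom; the qualitative shape has a single knee), evaluates its second
derivative on a grid, and takes $t_U$ where the curvature first re-enters
a near-zero band (10% of the maximum absolute curvature) after its
minimum, and $t_L$ just before the curvature turns positive. Sizes are
read off the *fitted* curve rather than the empirical rank vector: across
a near-vertical knee the spline interpolates the gap between the cell and
background populations instead of snapping to one population's edge.
Manual thresholds are always honoured from the configuration, and a curve
without curvature structure is rejected with instructions to supply them.

Cells below $t_L$ are labelled low-quality; the largest 75% above $t_U$
are labelled high-quality (the size-ranked reading of "top 75%" keeps the
labelling deterministic); the rest are unknown. Features are technical:
mitochondrial UMI fraction, mean reads per UMI, mean UMIs per gene,
fraction of single-molecule genes, intergenic read fraction, and an
optional unaligned-read fraction when supplied externally. Features are
standardized by median and MAD (the training set is size-biased, so
non-robust scaling would be dominated by the background class).

The classifier is a Gaussian kernel density estimate per class on the
first three components of a sparse robust PCA, with the normal-scale
bandwidth matrix
$H = (4/(d+2))^{2/(d+4)} n^{-2/(d+4)} \hat\Sigma$. The sparse robust PCA
is a grid projection-pursuit: each component maximizes the squared MAD of
the projection minus an $L_1$ penalty on the loadings (sparsity level
$\lambda = 1$; the penalty is zero exactly for axis-aligned directions),
searched by cyclic plane rotations over an angle grid and deflated between
components. The construction is deterministic and resistant to the label
noise that the size-based training set necessarily contains. Scores are
the posterior of the high-quality class under equal priors — the training
set's class proportions reflect the size split, not any meaningful prior.

Cells with extreme mitochondrial or intergenic fractions (above the 20%
trimmed mean plus four MADs; `stats::mad()` with its default consistency
constant) are handled before or after training: if either fraction
carries at least 5% of the absolute loading on any of the three
components, extreme cells are relabelled low-quality before training;
otherwise they are zeroed after scoring. When a fraction's MAD is zero —
typical when most background barcodes carry no mitochondrial molecule —
the rule is skipped entirely, since "extreme" is undefined for a
degenerate scale. Final filtering keeps large cells unless their score
falls below `quality_drop_lo` (0.1) and rescues small cells whose score
exceeds `quality_keep_hi` (0.9), subject to a minimum expressed-gene
count.

## The synthetic generator

`simulate_dataset()` emulates the phenomena the corrections target: a
Dirichlet-skewed UMI pool with extra mass on homopolymer-rich sequences;
per-read single-base UMI errors whose distinguishing base is drawn from a
low quality level (with a 20% high-quality admixture so that quality is
informative but not decisive); barcode splits rerouting 20% of an
affected cell's reads to a Hamming-1 child; background barcodes drawing
from the pooled expression profile — including mitochondrial transcripts,
as ambient RNA does — with small lognormal sizes; damaged cells with a
boosted mitochondrial share and fewer reads per molecule; and optional
two-species gene labels. Reads per molecule follow a shifted geometric
distribution with mean 4 — composition-based merging requires multi-read
molecules, and droplet libraries generally have them. Everything is
driven by one seed and every injected artefact is recorded in a ground
truth table.

What the generator does *not* emulate: PCR amplification lineages (errors
are independent per read), indel errors (the Hamming metric is assumed
throughout), doublets, chimeric molecules, or gene-length and GC biases.
Passing tests on this generator therefore demonstrate that each method
recovers the distortions it models, under the stated generative
assumptions — not that those assumptions exhaust real libraries.

## Problem sizes and study conditions

The saturated study library used by the correction-ordering checks has 20
cells of about 1000 molecules over 12 genes with 6-bp UMIs and a 1%
per-read error rate, placing the most expressed genes at roughly 6% of
the UMI pool — the regime where collision and error corrections matter
and where the baselines' blanket removal of adjacent UMIs visibly
over-prunes. The same library trimmed to 4 bp drives the
collision-adjustment comparison. Merge calibration uses 150 independent
cells in a deliberately dense 6-bp barcode space; power and the
cross-species audit use 60 cells with 30% barcode-split injection. The
classifier checks use 300 cells per class with 10% symmetric label
noise; its cross-validated sensitivity and specificity are measured
against the generator's true labels — with 10% label noise, agreement
with the noisy labels is capped near 90% by construction, and the claim
under test is recovery of the true classes despite the noise. At these
sizes the whole suite runs in minutes on one CPU.

## Known limitations

* All corrections degrade as per-gene saturation approaches the pool
  size; at 4-bp UMIs with genes beyond half the pool, even the Bayesian
  filter's training assumption (two-UMI adjacent genes are error pairs)
  starts to fail, because random adjacency becomes common. The package
  reports the ordering among methods faithfully in that regime, but no
  method recovers truth there.
* The quality-model training set requires at least one two-UMI adjacent
  gene; sparse, error-free libraries will not train, and the error
  message directs users to the cluster fallback.
* The Poisson composition test assumes independent compositions under the
  null; shared ambient RNA violates this mildly, making the test slightly
  conservative in the direction of extra merges between background
  barcodes.
* The knee detector assumes a single knee; libraries with multiple
  plateaus need manual thresholds, which every entry point accepts.
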