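# dropcount

Accurate molecular counts from droplet single-cell RNA-seq tag records.

Droplet protocols (inDrop, Drop-seq, 10x Chromium) estimate gene
expression as the number of distinct unique molecular identifiers (UMIs)
per gene per cell. Three technical artefacts distort that number, and a
fourth problem decides which barcodes to report at all:

* **UMI collisions** — two molecules of one gene draw the same UMI, so
  distinct UMIs under-count molecules. With `k` distinct UMIs observed
  from a pool of `m`, the uniform-pool estimate is `n = -m log(1 - k/m)`;
  real UMI usage is highly skewed, so dropcount instead builds the
  adjustment stepwise from the empirical UMI distribution:
  `n(k+1) = n(k) + 1/p(new)`, where
  `p(new) = Σ_i p(u_i) (1 - p(u_i))^{n(k)}`.
* **UMI sequence errors** — a single-base error fabricates a molecule at
  Hamming distance 1 from its parent. dropcount scores, for each target
  UMI, a posterior over how many of its lower-read Hamming-1 neighbours
  are errors, combining base-call quality likelihoods trained without
  labels (from genes carrying exactly two adjacent UMIs), a
  dynamic-programming prior on chance adjacency, a binomial model of
  erroneous reads, and an occupancy correction for errors colliding on
  one sequence. The published *cluster*, *cluster-neq* and *directional*
  heuristics are included as baselines.
* **Cell barcode errors** — a barcode error splits a cell, and the child
  barcode inherits exact gene–UMI pairs. dropcount tests the observed
  composition overlap `C` of each barcode pair against its expectation
  `EC` under independence with a Poisson tail `P(X ≥ C)`, Bonferroni
  adjusted, and merges accordingly (plus proximity-only and
  whitelist-based baselines).
* **Damaged / low-quality cells** — a noise-tolerant classifier scores
  every barcode from technical features (mitochondrial fraction, reads
  per UMI, UMIs per gene, single-molecule gene fraction, intergenic
  fraction): Gaussian KDE posteriors with normal-scale bandwidths on
  three sparse robust principal components, trained on labels taken from
  the barcode rank curve's knee.

A seed-deterministic synthetic droplet generator (`simulate_dataset()`)
produces libraries with known ground truth for every artefact, so the
whole pipeline is testable without downloads.

## Worked example

```r
library(dropcount)

cfg <- simulation_config(n_cells = 60, n_background = 200, n_genes = 12,
                         seed = 42, cell_size_meanlog = log(1000),
                         cell_size_sdlog = 0.25, umi_error_rate = 0.01)
sim <- simulate_dataset(cfg)

result <- run_pipeline(sim$records, run_config(
  umi_method = "bayesian", cb_method = "poisson",
  collision_adjustment = "empirical",
  mito_genes = sim$truth$mito_genes, seed = 42
))
result
#> <dropcount_result>
#>   matrix: 17 genes x 55 cells
#>   molecules: 64556, merges: 9
#>   cells kept: 55 of 260
glance(result)
#> # A tibble: 1 × 7
#>   n_genes n_cells n_molecules n_reads umis_removed cb_merges  seed
#>     <int>   <int>       <int>   <dbl>        <int>     <int> <int>
#> 1      17      55       64556  255589         3048         9    42
```

Of 260 barcodes (60 cells plus 200 empty droplets), the quality stage
keeps 55: the real cells minus the simulated damaged ones, with the
background discarded. The UMI stage removed 3048 erroneous UMIs and the
composition test merged 9 split barcodes back into their parents.

Because the generator records ground truth, each stage can be scored.
On this library the Bayesian filter identifies injected errors far more
precisely than the cluster baseline, which at this saturation removes
many genuine molecules:

```r
evaluate_against_truth(sim$records,
                       correct_umi_errors(sim$records, method = "bayesian"),
                       sim$truth)
#> # A tibble: 1 × 4
#>   precision recall    f1 count_rmse
#>       <dbl>  <dbl> <dbl>      <dbl>
#> 1     0.620  0.783 0.692       4.06
evaluate_against_truth(sim$records,
                       correct_umi_errors(sim$records, method = "cluster"),
                       sim$truth)
#> # A tibble: 1 × 4
#>   precision recall    f1 count_rmse
#>       <dbl>  <dbl> <dbl>      <dbl>
#> 1     0.138  0.886 0.239       20.1
```

The count matrix is written in Matrix Market form with barcode and
feature sidecars (`write_count_matrix()`), and `exec/dropcount` exposes
the same pipeline as a command line tool
(`dropcount correct --input records.tsv --out out/`, plus `simulate` and
`diagnose` subcommands).

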