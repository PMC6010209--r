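# Shared fixture builders. Everything is generated in code; expensive
# simulations are cached per session.

# Build a record tibble from parallel vectors; quals default to a constant
# 30 at every position.
make_records <- function(cb, umi, gene, reads, quals = NULL, intergenic = FALSE) {
  n <- length(umi)
  L <- nchar(umi[1])
  if (is.null(quals)) quals <- replicate(n, rep(30, L), simplify = FALSE)
  if (is.numeric(quals) && !is.list(quals)) quals <- replicate(n, rep(quals, L), simplify = FALSE)
  tibble::tibble(
    cb = rep_len(cb, n), umi = umi, gene = rep_len(gene, n),
    reads = as.numeric(rep_len(reads, n)), quals = quals,
    intergenic = rep_len(intergenic, n)
  )
}

# A gene/cell UMI group in the list form the filters consume.
make_group <- function(umis, reads, quals = NULL, cb = "c1", gene = "g1") {
  L <- nchar(umis[1])
  if (is.null(quals)) quals <- replicate(length(umis), rep(30, L), simplify = FALSE)
  list(cb = cb, gene = gene, umis = umis, reads = as.numeric(reads), quals = quals)
}

# A two-point quality model for posterior tests: support {15, 35}, errors
# concentrated at low quality.
toy_quality_model <- function(p_e = 0.05) {
  structure(
    list(support = c(15, 35), p_q = c(0.3, 0.7), p_q_err = c(0.8, 0.2),
         p_e = p_e, n_training_pairs = 10L),
    class = "umi_quality_model"
  )
}

# Write a record tibble to the on-disk TSV format.
write_records_tsv <- function(records, path) {
  out <- records
  out$quals <- vapply(out$quals, function(q) paste(q, collapse = ","), character(1))
  out$intergenic <- as.integer(out$intergenic)
  readr::write_tsv(out, path)
  path
}

# Session cache for expensive simulations shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# The saturated study dataset used by the correction-ordering checks:
# 6-bp UMIs, 1% per-read error rate, top genes at ~6% of the UMI pool.
saturated_sim <- function() {
  cached("saturated_sim", dropcount::simulate_dataset(
    dropcount::simulation_config(
      n_cells = 20, n_background = 100, n_genes = 12, seed = 5,
      cell_size_meanlog = log(1000), cell_size_sdlog = 0.25,
      umi_error_rate = 0.01
    )
  ))
}

saturated_corrections <- function() {
  cached("saturated_corrections", {
    sim <- saturated_sim()
    methods <- c("cluster", "cluster-neq", "directional", "bayesian")
    stats::setNames(
      lapply(methods, function(m) dropcount::correct_umi_errors(sim$records, method = m)),
      methods
    )
  })
}
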