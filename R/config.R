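# Run configuration: a validated named list mirroring the YAML config file.

#' Build a run configuration
#'
#' All pipeline stages read their tunables from this object. Every argument
#' has a sensible default; a YAML file with the same keys can be loaded with
#' [read_run_config()] and individual values overridden.
#'
#' @param umi_method UMI error correction method: one of `"none"`,
#'   `"cluster"`, `"cluster-neq"`, `"directional"`, `"bayesian"`.
#' @param collision_adjustment `"none"`, `"uniform"` or `"empirical"`.
#' @param cb_method Cellular-barcode merge method: `"none"`, `"simple"`,
#'   `"poisson"` or `"known"`.
#' @param cb_whitelist Optional path to a barcode whitelist (for `"known"`).
#' @param cb_max_hamming Maximum CB Hamming distance considered for merging.
#' @param cb_alpha Significance level for the Poisson composition test
#'   (applied after Bonferroni adjustment).
#' @param quality_enabled Run the cell-quality classifier stage.
#' @param quality_keep_hi,quality_drop_lo Score thresholds used by
#'   [filter_cells()].
#' @param quality_min_genes Minimal number of expressed genes per kept cell.
#' @param quality_manual_thresholds Optional numeric `c(t_l, t_u)` overriding
#'   the automatic rank-curve thresholds.
#' @param mito_genes Character vector of mitochondrial gene identifiers (or
#'   path to a one-per-line file).
#' @param umi_k_quantiles Quality quantization level for the Bayesian filter.
#' @param umi_dp_step Quantization step for the adjacency-prior cache.
#' @param umi_max_iterations Iteration cap for the Bayesian filter.
#' @param umi_directional_ratio Read-ratio of the directional baseline.
#' @param collision_negligible Skip collision adjustment when k/m is below
#'   this fraction.
#' @param seed Integer random seed recorded in all outputs.
#' @return A list of class `dropcount_config`.
#' @export
run_config <- function(umi_method = "bayesian",
                       collision_adjustment = "empirical",
                       cb_method = "poisson",
                       cb_whitelist = NULL,
                       cb_max_hamming = 2,
                       cb_alpha = 0.01,
                       quality_enabled = TRUE,
                       quality_keep_hi = 0.9,
                       quality_drop_lo = 0.1,
                       quality_min_genes = 10,
                       quality_manual_thresholds = NULL,
                       mito_genes = character(),
                       umi_k_quantiles = 15,
                       umi_dp_step = 0.01,
                       umi_max_iterations = 10,
                       umi_directional_ratio = 2,
                       collision_negligible = 0.01,
                       seed = 42L) {
  cfg <- list(
    umi_method = match.arg(umi_method, c("none", "cluster", "cluster-neq", "directional", "bayesian")),
    collision_adjustment = match.arg(collision_adjustment, c("none", "uniform", "empirical")),
    cb_method = match.arg(cb_method, c("none", "simple", "poisson", "known")),
    cb_whitelist = cb_whitelist,
    cb_max_hamming = as.integer(cb_max_hamming),
    cb_alpha = cb_alpha,
    quality_enabled = isTRUE(quality_enabled),
    quality_keep_hi = quality_keep_hi,
    quality_drop_lo = quality_drop_lo,
    quality_min_genes = as.integer(quality_min_genes),
    quality_manual_thresholds = quality_manual_thresholds,
    mito_genes = mito_genes,
    umi_k_quantiles = as.integer(umi_k_quantiles),
    umi_dp_step = umi_dp_step,
    umi_max_iterations = as.integer(umi_max_iterations),
    umi_directional_ratio = umi_directional_ratio,
    collision_negligible = collision_negligible,
    seed = as.integer(seed)
  )
  if (length(cfg$mito_genes) == 1 && file.exists(cfg$mito_genes)) {
    cfg$mito_genes <- readLines(cfg$mito_genes)
  }
  structure(cfg, class = "dropcount_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to [run_config()]
#' defaults. Additional `...` overrides win over the file.
#'
#' @param path YAML file path.
#' @param ... Named overrides applied on top of the file.
#' @return A `dropcount_config` list.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @export
print.dropcount_config <- function(x, ...) {
  cat("<dropcount run configuration>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.null(v)) v <- "<null>"
    if (length(v) > 4) v <- c(v[1:4], "...")
    cat(sprintf("  %-22s %s\n", k, paste(v, collapse = ", ")))
  }
  invisible(x)
}
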