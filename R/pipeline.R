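# End-to-end orchestration: records -> UMI error correction -> CB merge ->
# collision adjustment -> quality classification -> count matrix + report.
#
# Stage order: UMI errors are removed first so that barcode merging
# compares error-free gene-UMI compositions; collision adjustment runs
# after merging because merges change gene sizes; quality classification
# runs last on the corrected data. Every stage can be disabled from the
# configuration and disabling a stage never alters earlier stages' outputs.

#' Run the full correction pipeline
#'
#' @param records A molecule record tibble (from [read_records()] or
#'   [simulate_dataset()]).
#' @param config A `dropcount_config` from [run_config()].
#' @param out_prefix Optional path prefix; when supplied the count matrix,
#'   audits and report are written there.
#' @return A list of class `dropcount_result`: `matrix` (final count
#'   matrix), `records` (corrected records), `umi_audit`, `merge_plan`,
#'   `thresholds`, `cell_table` (per-cell sizes, features, scores, status),
#'   `report`, `config`.
#' @export
run_pipeline <- function(records, config = run_config(), out_prefix = NULL) {
  set.seed(config$seed)
  stage_stats <- list()

  dist <- if (nrow(records) > 0) estimate_umi_distribution(records) else NULL

  # 1. UMI sequence error correction -------------------------------------
  umi_audit <- NULL
  if (config$umi_method != "none" && nrow(records) > 0) {
    records <- correct_umi_errors(
      records,
      method = config$umi_method,
      dist = dist,
      k_quantiles = config$umi_k_quantiles,
      dp_step = config$umi_dp_step,
      max_iterations = config$umi_max_iterations,
      directional_ratio = config$umi_directional_ratio
    )
    umi_audit <- attr(records, "audit")
    stage_stats$umi_correction <- list(
      method = config$umi_method,
      removed_umis = nrow(umi_audit)
    )
  }

  # 2. Cellular barcode merging ------------------------------------------
  plan <- empty_merge_plan(config$cb_method)
  if (config$cb_method != "none" && nrow(records) > 0) {
    ctable <- if (config$collision_adjustment == "empirical" && !is.null(dist)) {
      max_gene <- records %>%
        filter(!.data$intergenic) %>%
        count(.data$cb, .data$gene) %>%
        pull(.data$n) %>%
        max()
      build_collision_table(dist, max_k = min(max_gene, dist$pool_size - 1L))
    }
    plan <- switch(
      config$cb_method,
      "simple" = merge_simple(records, max_hamming = config$cb_max_hamming),
      "poisson" = merge_poisson(records, dist = dist, table = ctable,
                                max_hamming = config$cb_max_hamming,
                                alpha = config$cb_alpha),
      "known" = {
        if (is.null(config$cb_whitelist)) abort("cb_method 'known' needs a whitelist")
        wl <- if (length(config$cb_whitelist) == 1 && file.exists(config$cb_whitelist)) {
          read_whitelist(config$cb_whitelist)
        } else {
          config$cb_whitelist
        }
        merge_known_barcodes(records, wl, dist = dist, table = ctable,
                             max_hamming = config$cb_max_hamming)
      }
    )
    records <- apply_merge(records, plan)
    stage_stats$cb_merge <- list(method = config$cb_method, merges = nrow(plan))
  }

  # 3. Collision adjustment ----------------------------------------------
  mat <- count_matrix(records)
  if (config$collision_adjustment != "none" && length(mat@x) > 0) {
    max_k <- as.integer(max(mat@x))
    table <- if (config$collision_adjustment == "uniform") {
      uniform_collision_table(4^umi_length(records),
                              max_k = min(max_k, 4^umi_length(records) - 1))
    } else {
      d <- estimate_umi_distribution(records)
      build_collision_table(d, max_k = min(max_k, d$pool_size - 1L))
    }
    mat <- adjust_counts(mat, table, negligible = config$collision_negligible)
    stage_stats$collision_adjustment <- list(
      mode = config$collision_adjustment,
      max_observed = max_k
    )
  }

  # 4. Cell quality classification ---------------------------------------
  thresholds <- NULL
  cell_table <- NULL
  if (config$quality_enabled && nrow(records) > 0) {
    sizes_tbl <- records %>%
      filter(!.data$intergenic) %>%
      count(.data$cb, name = "size")
    sizes <- setNames(sizes_tbl$size, sizes_tbl$cb)
    if (!is.null(config$quality_manual_thresholds)) {
      mt <- sort(config$quality_manual_thresholds)
      thresholds <- tibble(t_l = mt[1], t_u = mt[2])
    } else if (length(sizes) >= 100) {
      thresholds <- tryCatch(size_thresholds(sizes), error = function(e) {
        warn(conditionMessage(e))
        NULL
      })
    }
    if (!is.null(thresholds)) {
      labels <- initial_labels(sizes, thresholds)
      features <- extract_features(records, mito_genes = config$mito_genes)
      clf <- tryCatch(
        train_quality_classifier(features, labels),
        error = function(e) {
          warn(conditionMessage(e))
          NULL
        }
      )
      if (!is.null(clf)) {
        scores <- score_cells(clf, features)
        genes_per_cell <- records %>%
          filter(!.data$intergenic) %>%
          group_by(.data$cb) %>%
          summarise(g = dplyr::n_distinct(.data$gene), .groups = "drop")
        gpc <- setNames(genes_per_cell$g, genes_per_cell$cb)
        cell_table <- filter_cells(
          scores, sizes, thresholds,
          keep_hi = config$quality_keep_hi,
          drop_lo = config$quality_drop_lo,
          genes_per_cell = gpc,
          min_genes = config$quality_min_genes
        ) %>%
          left_join(labels %>% select("cb", initial_label = "label"), by = "cb") %>%
          left_join(features, by = "cb", suffix = c("", ".feat"))
        mat <- mat[, colnames(mat) %in% cell_table$cb[cell_table$kept], drop = FALSE]
        stage_stats$quality <- list(
          t_l = thresholds$t_l, t_u = thresholds$t_u,
          kept = sum(cell_table$kept),
          rescued = sum(cell_table$status == "rescued"),
          filtered = sum(!cell_table$kept),
          score_histogram = as.numeric(table(cut(cell_table$score, seq(0, 1, 0.1),
                                                 include.lowest = TRUE)))
        )
      }
    }
  }

  report <- run_report(records, config, stage_stats)
  result <- structure(
    list(
      matrix = mat, records = records, umi_audit = umi_audit,
      merge_plan = plan, thresholds = thresholds, cell_table = cell_table,
      report = report, config = config
    ),
    class = "dropcount_result"
  )
  if (!is.null(out_prefix)) {
    write_count_matrix(mat, out_prefix)
    write_run_report(report, out_prefix)
    if (!is.null(umi_audit)) {
      readr::write_tsv(umi_audit, paste0(out_prefix, "umi_audit.tsv"))
    }
    if (nrow(plan) > 0) readr::write_tsv(plan, paste0(out_prefix, "merge_plan.tsv"))
    if (!is.null(cell_table)) {
      readr::write_tsv(cell_table, paste0(out_prefix, "cells.tsv"))
    }
  }
  result
}

#' @export
print.dropcount_result <- function(x, ...) {
  cat("<dropcount_result>\n")
  cat(sprintf("  matrix: %d genes x %d cells\n", nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  molecules: %d, merges: %d\n", nrow(x$records), nrow(x$merge_plan)))
  if (!is.null(x$cell_table)) {
    cat(sprintf("  cells kept: %d of %d\n", sum(x$cell_table$kept), nrow(x$cell_table)))
  }
  invisible(x)
}

#' Tidy summaries of a pipeline result
#'
#' @param x A `dropcount_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-cell table (sizes, scores, status);
#'   `glance()`: one-row tibble of headline statistics.
#' @export
tidy.dropcount_result <- function(x, ...) {
  if (!is.null(x$cell_table)) return(x$cell_table)
  x$records %>%
    filter(!.data$intergenic) %>%
    count(.data$cb, name = "size")
}

#' @rdname tidy.dropcount_result
#' @export
glance.dropcount_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x$matrix),
    n_cells = ncol(x$matrix),
    n_molecules = nrow(x$records),
    n_reads = sum(x$records$reads),
    umis_removed = if (is.null(x$umi_audit)) 0L else nrow(x$umi_audit),
    cb_merges = nrow(x$merge_plan),
    seed = x$config$seed
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
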