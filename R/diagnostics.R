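# Diagnostics and validation machinery: edit-distance distribution
# comparison, UMI trimming and the trimming benchmark, rank-curve tables,
# adjacency excess and the machine-readable run report.

#' Observed Hamming-distance distribution between UMIs of the same gene
#'
#' All pairwise Hamming distances within each cell-gene group, pooled
#' across the dataset and normalized. Groups larger than `max_group` UMIs
#' are subsampled (seeded) to bound the quadratic cost.
#'
#' @param records A molecule record tibble.
#' @param max_group Cap on UMIs per group entering the pairwise pool.
#' @param seed Seed for the subsampling.
#' @return A tibble: distance, probability.
#' @export
observed_edit_distribution <- function(records, max_group = 1000, seed = 1L) {
  L <- umi_length(records)
  groups <- umi_groups(records, min_umis = 2L)
  if (length(groups) == 0) abort("no gene has two or more UMIs")
  counts <- numeric(L + 1)
  set.seed(seed)
  for (g in groups) {
    umis <- g$umis
    if (length(umis) > max_group) umis <- sample(umis, max_group)
    d <- hamming_matrix(umis)
    d <- d[upper.tri(d)]
    counts <- counts + tabulate(d + 1L, nbins = L + 1L)
  }
  tibble(distance = 0:L, probability = counts / sum(counts))
}

#' Theoretical Hamming-distance distribution under a common UMI pool
#'
#' Monte-Carlo distribution of the Hamming distance between two independent
#' draws from the UMI distribution.
#'
#' @param dist An `umi_distribution`.
#' @param n_pairs Number of sampled pairs (>= 1e4).
#' @param seed Random seed.
#' @return A tibble: distance, probability.
#' @export
theoretical_edit_distribution <- function(dist, n_pairs = 1e5, seed = 1L) {
  if (n_pairs < 1e4) abort("n_pairs must be at least 1e4")
  set.seed(seed)
  L <- dist$umi_length
  seqs <- names(dist$probs)
  a <- sample(seqs, n_pairs, replace = TRUE, prob = dist$probs)
  b <- sample(seqs, n_pairs, replace = TRUE, prob = dist$probs)
  am <- do.call(rbind, strsplit(a, "", fixed = TRUE))
  bm <- do.call(rbind, strsplit(b, "", fixed = TRUE))
  d <- rowSums(am != bm)
  tibble(distance = 0:L, probability = tabulate(d + 1L, nbins = L + 1L) / n_pairs)
}

#' Per-distance relative difference between observed and theoretical
#' profiles
#'
#' |P(ED = k) - P*(ED = k)| / P*(ED = k); distances with zero theoretical
#' mass are reported as `NA`.
#'
#' @param observed,theoretical Tibbles from the two distribution functions.
#' @return A tibble: distance, observed, theoretical, relative_difference.
#' @export
edit_distance_relative_difference <- function(observed, theoretical) {
  if (!identical(observed$distance, theoretical$distance)) {
    abort("distance supports are not aligned")
  }
  p_obs <- observed$probability
  p_theo <- theoretical$probability
  tibble(
    distance = observed$distance,
    observed = p_obs,
    theoretical = p_theo,
    relative_difference = ifelse(p_theo > 0, abs(p_obs - p_theo) / p_theo, NA_real_)
  )
}

#' Trim UMIs to a shorter length
#'
#' Truncates sequences and quality vectors from the chosen side; records
#' whose trimmed (cb, umi, gene) keys collide are merged with reads summed
#' and read-weighted mean qualities — shortening UMIs this way naturally
#' creates collision events for benchmarking.
#'
#' @param records A molecule record tibble.
#' @param new_length Target UMI length (1 <= new_length < current length).
#' @param side `"back"` (drop trailing bases) or `"front"`.
#' @return The trimmed, re-aggregated record tibble.
#' @export
trim_umis <- function(records, new_length, side = c("back", "front")) {
  side <- match.arg(side)
  L <- umi_length(records)
  if (new_length < 1 || new_length >= L) {
    abort(sprintf("new_length must be in [1, %d)", L))
  }
  keep_idx <- if (side == "back") 1:new_length else (L - new_length + 1):L
  records$umi <- substr(records$umi,
                        min(keep_idx), max(keep_idx))
  records$quals <- lapply(records$quals, function(q) q[keep_idx])
  aggregate_records(records)
}

#' UMI trimming benchmark
#'
#' Treats full-length counts (after a reference correction, cluster by
#' default) as ground truth, trims UMIs to each requested length, applies
#' each correction method plus collision adjustment, and reports the
#' percentage count error per cell-gene entry with its expression bin
#' (log2 bins of the benchmark count).
#'
#' @param records A molecule record tibble at full UMI length.
#' @param lengths Integer vector of trim lengths.
#' @param methods Character vector of correction methods to benchmark.
#' @param adjustments Collision-adjustment modes to cross with the methods
#'   (subset of "none", "uniform", "empirical").
#' @param side Trimming side.
#' @param benchmark_method Correction applied at full length to obtain the
#'   reference counts.
#' @return A tibble: length, method, adjustment, cb, gene, benchmark,
#'   estimate, percent_error, expression_bin.
#' @export
trimming_benchmark <- function(records, lengths,
                               methods = c("none", "cluster", "bayesian"),
                               adjustments = "none",
                               side = "back",
                               benchmark_method = "cluster") {
  bench_rec <- correct_umi_errors(records, method = benchmark_method)
  bench <- bench_rec %>%
    filter(!.data$intergenic) %>%
    count(.data$cb, .data$gene, name = "benchmark")
  out <- NULL
  for (len in lengths) {
    trimmed <- trim_umis(records, len, side = side)
    for (method in methods) {
      corrected <- correct_umi_errors(trimmed, method = method)
      for (adj in adjustments) {
        counts <- corrected %>%
          filter(!.data$intergenic) %>%
          count(.data$cb, .data$gene, name = "estimate")
        if (adj != "none") {
          tab <- if (adj == "uniform") {
            uniform_collision_table(4^len, max_k = min(max(counts$estimate), 4^len - 1))
          } else {
            d <- estimate_umi_distribution(corrected)
            build_collision_table(d, max_k = min(max(counts$estimate), d$pool_size))
          }
          counts$estimate <- collision_lookup_capped(tab, counts$estimate)
        }
        merged <- bench %>%
          left_join(counts, by = c("cb", "gene")) %>%
          mutate(
            estimate = ifelse(is.na(.data$estimate), 0, .data$estimate),
            percent_error = 100 * (.data$estimate - .data$benchmark) / .data$benchmark,
            expression_bin = floor(log2(.data$benchmark))
          )
        out <- bind_rows(out, merged %>%
                           mutate(length = len, method = method, adjustment = adj))
      }
    }
  }
  out
}

# Lookup that clamps k beyond the table to the last tabulated value
# (saturated pools during benchmarking).
collision_lookup_capped <- function(table, k) {
  kk <- pmin(as.integer(round(k)), length(table$n_of_k))
  collision_lookup(table, kk)
}

#' Barcode rank and molecular-mass curve tables
#'
#' @param sizes Per-barcode molecule counts.
#' @param n_bins Bins for the molecular-mass curve.
#' @return A list of two tibbles: `rank_curve` (rank, size) and
#'   `mass_curve` (log-size bin midpoint, total molecules in bin).
#' @export
rank_curves <- function(sizes, n_bins = 30) {
  sizes <- sort(sizes[sizes > 0], decreasing = TRUE)
  rank_curve <- tibble(rank = seq_along(sizes), size = sizes)
  ls <- log10(sizes)
  breaks <- seq(min(ls), max(ls), length.out = n_bins + 1)
  if (diff(range(ls)) == 0) breaks <- c(ls[1] - 0.5, ls[1] + 0.5)
  bin <- cut(ls, breaks, include.lowest = TRUE)
  mass <- tapply(sizes, bin, sum, default = 0)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  mass_curve <- tibble(log10_size = mids[seq_along(mass)], mass = as.numeric(mass))
  list(rank_curve = rank_curve, mass_curve = mass_curve)
}

#' Excess of adjacent UMI pairs over the independent-draw expectation
#'
#' Counts Hamming-1 UMI pairs within cell-gene groups and divides by the
#' expected number under independent draws from the UMI distribution given
#' the observed group sizes. Ratios well above 1 indicate sequence errors.
#'
#' @param records A molecule record tibble.
#' @param dist An `umi_distribution` (estimated from `records` if missing).
#' @param n_sim Monte-Carlo draws per group-size stratum for the
#'   expectation.
#' @param seed Random seed.
#' @return A tibble: observed_pairs, expected_pairs, ratio (NA when no
#'   multi-UMI group exists).
#' @export
adjacency_excess <- function(records, dist = NULL, n_sim = 200, seed = 1L) {
  groups <- umi_groups(records, min_umis = 2L)
  if (length(groups) == 0) {
    return(tibble(observed_pairs = 0, expected_pairs = NA_real_, ratio = NA_real_))
  }
  if (is.null(dist)) dist <- estimate_umi_distribution(records)
  observed <- sum(vapply(groups, function(g) {
    d <- hamming_matrix(g$umis)
    sum(d[upper.tri(d)] == 1L)
  }, numeric(1)))
  set.seed(seed)
  size_tab <- table(vapply(groups, function(g) length(g$umis), integer(1)))
  seqs <- names(dist$probs)
  expected <- 0
  for (nm in names(size_tab)) {
    s <- as.integer(nm)
    reps <- size_tab[[nm]]
    sims <- vapply(seq_len(n_sim), function(i) {
      u <- unique(sample(seqs, s, replace = TRUE, prob = dist$probs))
      d <- hamming_matrix(u)
      sum(d[upper.tri(d)] == 1L)
    }, numeric(1))
    expected <- expected + reps * mean(sims)
  }
  tibble(
    observed_pairs = observed,
    expected_pairs = expected,
    ratio = if (expected > 0) observed / expected else NA_real_
  )
}

#' Assemble the machine-readable run report
#'
#' @param records Final record tibble.
#' @param config The `dropcount_config` used.
#' @param stage_stats Named list of per-stage summaries (counts of removed
#'   UMIs, merges, thresholds, score histogram ...).
#' @return A list ready for JSON serialization.
#' @export
run_report <- function(records, config, stage_stats = list()) {
  umi_stats <- if (nrow(records) > 0) {
    d <- estimate_umi_distribution(records)
    list(
      umi_length = d$umi_length,
      observed_sequences = d$pool_size,
      possible_sequences = d$n_possible,
      max_probability = max(d$probs)
    )
  } else {
    list(umi_length = 0, observed_sequences = 0,
         possible_sequences = 0, max_probability = 0)
  }
  c(
    list(
      n_molecules = nrow(records),
      n_reads = sum(records$reads),
      n_cells = length(unique(records$cb)),
      n_genes = length(unique(records$gene[!records$intergenic])),
      umi_distribution = umi_stats,
      seed = config$seed,
      config = unclass(config)[!vapply(unclass(config), is.null, logical(1))]
    ),
    stage_stats
  )
}

#' Write a run report as JSON plus a text summary
#'
#' @param report List from [run_report()].
#' @param out_prefix Path prefix for `report.json` and `report.txt`.
#' @return Invisibly, the two paths.
#' @export
write_run_report <- function(report, out_prefix) {
  paths <- paste0(out_prefix, c("report.json", "report.txt"))
  jsonlite::write_json(report, paths[1], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lines <- c(
    "dropcount run report",
    sprintf("molecules: %s  reads: %s  cells: %s  genes: %s",
            report$n_molecules, report$n_reads, report$n_cells, report$n_genes),
    sprintf("seed: %s", report$seed)
  )
  writeLines(lines, paths[2])
  invisible(paths)
}
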