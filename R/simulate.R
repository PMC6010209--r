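# Seed-deterministic synthetic droplet datasets with ground truth.
#
# The generator emulates the phenomena the correction stages target:
#   * a skewed UMI pool with low-complexity (homopolymer-enriched) outliers;
#   * per-read single-base UMI errors whose distinguishing base usually has
#     lower call quality (a configurable fraction keeps high quality, so
#     quality is informative but not decisive);
#   * cell-barcode errors splitting part of a parent cell's reads into a
#     Hamming-close child barcode that shares exact gene-UMI pairs;
#   * empty-droplet background barcodes drawing from the pooled expression
#     profile with small lognormal sizes;
#   * damaged cells with boosted mitochondrial load and fewer reads per
#     molecule; and optional two-species gene labels for merge audits.

#' Configuration for the synthetic droplet generator
#'
#' Defaults describe a small but saturated library: 6-bp UMIs, few highly
#' expressed genes so that per-gene UMI counts are an appreciable fraction
#' of the pool, 1% per-read UMI error rate, and a background population a
#' few times larger than the real one.
#'
#' @param n_cells Number of real cells.
#' @param n_background Number of empty-droplet barcodes.
#' @param n_genes Number of (non-mitochondrial) genes.
#' @param n_mito_genes Number of mitochondrial genes.
#' @param expression_power Power-law exponent of gene magnitudes.
#' @param umi_length UMI length L (pool 4^L; L <= 8).
#' @param pool_concentration Dirichlet concentration of the UMI pool
#'   (smaller = more skewed).
#' @param homopolymer_weight Extra log-mass per unit homopolymer-run
#'   fraction (0 = no low-complexity enrichment).
#' @param umi_error_rate Per-read probability of a single-base UMI error.
#' @param quality_high,quality_low Mean Phred levels of correct and
#'   erroneous base calls.
#' @param quality_sd Gaussian jitter of quality values.
#' @param high_quality_error_fraction Fraction of error bases receiving the
#'   high quality level.
#' @param cell_size_meanlog,cell_size_sdlog Lognormal molecule counts of
#'   real cells.
#' @param background_size_meanlog,background_size_sdlog Lognormal molecule
#'   counts of background barcodes.
#' @param reads_mean Mean of the shifted-geometric reads-per-molecule
#'   distribution.
#' @param cb_length Cell-barcode length.
#' @param cb_error_rate Fraction of real cells whose barcode spawns an
#'   erroneous child.
#' @param cb_split_fraction Fraction of an affected cell's reads rerouted
#'   to the child barcode.
#' @param cb_max_distance Hamming distance of injected CB errors (1 or 2).
#' @param damaged_fraction Fraction of real cells marked damaged.
#' @param damaged_mito_boost Mitochondrial molecule share in damaged cells.
#' @param mito_baseline Mitochondrial share in healthy cells.
#' @param damaged_reads_mean Reads-per-molecule mean in damaged cells.
#' @param two_species Label genes/cells with two species for merge audits.
#' @param intergenic_fraction Fraction of additional intergenic reads per
#'   cell (carried as a pseudo-gene record).
#' @param seed Random seed (mandatory).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 50,
                              n_background = 300,
                              n_genes = 40,
                              n_mito_genes = 5,
                              expression_power = 0.8,
                              umi_length = 6,
                              pool_concentration = 2,
                              homopolymer_weight = 2,
                              umi_error_rate = 0.01,
                              quality_high = 35,
                              quality_low = 10,
                              quality_sd = 2,
                              high_quality_error_fraction = 0.2,
                              cell_size_meanlog = log(800),
                              cell_size_sdlog = 0.4,
                              background_size_meanlog = log(20),
                              background_size_sdlog = 0.6,
                              reads_mean = 4,
                              cb_length = 10,
                              cb_error_rate = 0.15,
                              cb_split_fraction = 0.2,
                              cb_max_distance = 1,
                              damaged_fraction = 0.1,
                              damaged_mito_boost = 0.4,
                              mito_baseline = 0.05,
                              damaged_reads_mean = 1.5,
                              two_species = FALSE,
                              intergenic_fraction = 0.02,
                              seed = 1L) {
  cfg <- as.list(environment())
  rates <- c("umi_error_rate", "cb_error_rate", "cb_split_fraction",
             "damaged_fraction", "damaged_mito_boost", "mito_baseline",
             "high_quality_error_fraction", "intergenic_fraction")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) abort(sprintf("%s must be in [0, 1]", r))
  }
  if (is.null(cfg$seed)) abort("seed is mandatory")
  structure(cfg, class = "simulation_config")
}

#' Sample a skewed UMI pool
#'
#' Probabilities over all 4^L sequences: Dirichlet-distributed (gamma
#' draws) with extra mass on low-complexity sequences, giving the heavy
#' right tail and homopolymer enrichment seen in droplet libraries.
#'
#' @param cfg A `simulation_config` (fields umi_length, pool_concentration,
#'   homopolymer_weight, seed are used).
#' @return An `umi_distribution` over the full pool.
#' @export
sample_umi_pool <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$umi_length
  seqs <- all_sequences(L)
  w <- rgamma(length(seqs), shape = cfg$pool_concentration, rate = 1)
  if (cfg$homopolymer_weight > 0) {
    run_frac <- vapply(seqs, function(s) {
      r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
      max(r$lengths) / L
    }, numeric(1))
    w <- w * exp(cfg$homopolymer_weight * run_frac)
  }
  umi_distribution(setNames(w / sum(w), seqs), L)
}

shifted_geometric <- function(n, mean) {
  mean <- rep_len(pmax(mean, 1), n)
  out <- rep(1L, n)
  big <- mean > 1
  out[big] <- 1L + rgeom(sum(big), prob = 1 / mean[big])
  out
}

#' Simulate a droplet dataset with ground truth
#'
#' @param cfg A `simulation_config`.
#' @return A list: `records` (molecule record tibble), `truth` (list with
#'   `molecules`, `umi_errors`, `cb_errors`, `cells`, `pool`).
#' @export
simulate_dataset <- function(cfg) {
  pool <- sample_umi_pool(cfg)
  set.seed(cfg$seed + 1L)
  L <- cfg$umi_length
  pool_seqs <- names(pool$probs)

  n_species_genes <- if (cfg$two_species) ceiling(cfg$n_genes / 2) else cfg$n_genes
  genes <- if (cfg$two_species) {
    c(sprintf("hsA_g%03d", seq_len(n_species_genes)),
      sprintf("mmB_g%03d", seq_len(cfg$n_genes - n_species_genes)))
  } else {
    sprintf("g%03d", seq_len(cfg$n_genes))
  }
  species_of_gene <- if (cfg$two_species) {
    setNames(ifelse(startsWith(genes, "hsA"), "A", "B"), genes)
  } else {
    setNames(rep("A", length(genes)), genes)
  }
  mito_genes <- if (cfg$n_mito_genes > 0) sprintf("mt-%02d", seq_len(cfg$n_mito_genes)) else character()
  gene_prob <- seq_along(genes)^(-cfg$expression_power)
  gene_prob <- gene_prob / sum(gene_prob)
  mito_prob <- rep(1 / max(cfg$n_mito_genes, 1), cfg$n_mito_genes)

  # barcodes: unique real cells, then background
  n_cb <- cfg$n_cells + cfg$n_background
  cbs <- character(0)
  while (length(cbs) < n_cb) {
    cbs <- unique(c(cbs, random_sequences(n_cb - length(cbs) + 10, cfg$cb_length)))
  }
  cbs <- cbs[seq_len(n_cb)]
  real_cbs <- cbs[seq_len(cfg$n_cells)]
  bg_cbs <- cbs[-seq_len(cfg$n_cells)]

  damaged <- rep(FALSE, cfg$n_cells)
  if (cfg$damaged_fraction > 0 && cfg$n_cells > 0) {
    damaged[sample(cfg$n_cells, round(cfg$damaged_fraction * cfg$n_cells))] <- TRUE
  }
  species_of_cell <- if (cfg$two_species) {
    sample(c("A", "B"), cfg$n_cells, replace = TRUE)
  } else {
    rep("A", cfg$n_cells)
  }

  mol <- list()
  for (ci in seq_len(cfg$n_cells)) {
    size <- max(2L, as.integer(round(rlnorm(1, cfg$cell_size_meanlog, cfg$cell_size_sdlog))))
    mito_share <- if (damaged[ci]) cfg$damaged_mito_boost else cfg$mito_baseline
    n_mito <- if (cfg$n_mito_genes > 0) rbinom(1, size, mito_share) else 0L
    gpool <- genes[species_of_gene == species_of_cell[ci]]
    gprob <- gene_prob[species_of_gene == species_of_cell[ci]]
    g <- c(
      sample(gpool, size - n_mito, replace = TRUE, prob = gprob),
      if (n_mito > 0) sample(mito_genes, n_mito, replace = TRUE, prob = mito_prob)
    )
    mol[[ci]] <- tibble(
      cb = real_cbs[ci], gene = g,
      umi = sample(pool_seqs, size, replace = TRUE, prob = pool$probs),
      damaged = damaged[ci]
    )
  }
  for (bi in seq_len(cfg$n_background)) {
    size <- max(1L, as.integer(round(rlnorm(1, cfg$background_size_meanlog, cfg$background_size_sdlog))))
    # ambient RNA carries the pooled profile, mitochondrial transcripts included
    n_mito <- if (cfg$n_mito_genes > 0) rbinom(1, size, cfg$mito_baseline) else 0L
    g <- c(
      sample(genes, size - n_mito, replace = TRUE, prob = gene_prob),
      if (n_mito > 0) sample(mito_genes, n_mito, replace = TRUE, prob = mito_prob)
    )
    mol[[cfg$n_cells + bi]] <- tibble(
      cb = bg_cbs[bi],
      gene = g,
      umi = sample(pool_seqs, size, replace = TRUE, prob = pool$probs),
      damaged = FALSE
    )
  }
  molecules <- bind_rows(mol)
  molecules$reads <- shifted_geometric(nrow(molecules),
                                       ifelse(molecules$damaged,
                                              cfg$damaged_reads_mean, cfg$reads_mean))

  # per-read UMI errors: each read is independently misread at one position
  err_reads <- rbinom(nrow(molecules), molecules$reads, cfg$umi_error_rate)
  molecules$kept_reads <- molecules$reads - err_reads
  err_src <- rep(seq_len(nrow(molecules)), err_reads)
  umi_error_rows <- NULL
  if (length(err_src) > 0) {
    pos <- sample(L, length(err_src), replace = TRUE)
    shift <- sample(3, length(err_src), replace = TRUE)
    parent <- molecules$umi[err_src]
    old_base <- substr(parent, pos, pos)
    new_base <- vapply(seq_along(err_src), function(i) {
      setdiff(DNA_BASES, old_base[i])[shift[i]]
    }, character(1))
    err_umi <- parent
    substr(err_umi, pos, pos) <- new_base
    umi_error_rows <- tibble(
      cb = molecules$cb[err_src], gene = molecules$gene[err_src],
      parent_umi = parent, error_umi = err_umi,
      position = pos, reads = 1L
    )
  }

  # assemble records: surviving parent reads + error reads, with qualities
  qual_vec <- function(n, level, sd) pmax(2, rnorm(n, level, sd))
  parent_rec <- molecules %>%
    filter(.data$kept_reads > 0) %>%
    mutate(reads = .data$kept_reads) %>%
    select("cb", "umi", "gene", "reads")
  parent_rec$quals <- lapply(seq_len(nrow(parent_rec)), function(i) {
    qual_vec(L, cfg$quality_high, cfg$quality_sd)
  })
  rec_list <- list(parent_rec)
  if (!is.null(umi_error_rows)) {
    err_rec <- umi_error_rows %>%
      select("cb", umi = "error_umi", "gene", "reads", "position")
    hi_q <- runif(nrow(err_rec)) < cfg$high_quality_error_fraction
    err_rec$quals <- lapply(seq_len(nrow(err_rec)), function(i) {
      q <- qual_vec(L, cfg$quality_high, cfg$quality_sd)
      lvl <- if (hi_q[i]) cfg$quality_high else cfg$quality_low
      q[err_rec$position[i]] <- max(2, rnorm(1, lvl, cfg$quality_sd))
      q
    })
    rec_list <- c(rec_list, list(err_rec %>% select(-"position")))
  }
  records <- bind_rows(rec_list)
  records$intergenic <- FALSE

  # intergenic reads per cell, carried as a pseudo-gene record
  if (cfg$intergenic_fraction > 0) {
    per_cb <- records %>% group_by(.data$cb) %>% summarise(r = sum(.data$reads), .groups = "drop")
    ig_reads <- rbinom(nrow(per_cb), pmax(1L, as.integer(per_cb$r)), cfg$intergenic_fraction)
    keep <- ig_reads > 0
    if (any(keep)) {
      ig <- tibble(
        cb = per_cb$cb[keep],
        umi = strrep("A", L), gene = "__intergenic__",
        reads = as.numeric(ig_reads[keep]),
        quals = replicate(sum(keep), qual_vec(L, cfg$quality_high, cfg$quality_sd),
                          simplify = FALSE),
        intergenic = TRUE
      )
      records <- bind_rows(records, ig)
    }
  }

  # cell-barcode errors: reroute part of affected cells' reads to a child CB
  cb_error_rows <- NULL
  if (cfg$cb_error_rate > 0 && cfg$n_cells > 0) {
    n_err <- round(cfg$cb_error_rate * cfg$n_cells)
    if (n_err > 0) {
      parents <- sample(real_cbs, n_err)
      existing <- c(cbs)
      for (p in parents) {
        child <- NA_character_
        for (attempt in seq_len(50)) {
          cand_pool <- if (cfg$cb_max_distance >= 2 && attempt > 25) {
            hamming2_neighbors(p)
          } else {
            hamming1_neighbors(p)
          }
          cand <- sample(cand_pool, 1)
          if (!cand %in% existing) {
            child <- cand
            break
          }
        }
        if (is.na(child)) next
        existing <- c(existing, child)
        idx <- which(records$cb == p)
        take <- rbinom(length(idx), records$reads[idx], cfg$cb_split_fraction)
        moved <- which(take > 0)
        if (length(moved) == 0) {
          # guarantee the child exists: move one read of the largest record
          moved <- which.max(records$reads[idx])
          take[moved] <- pmin(1, records$reads[idx][moved])
        }
        child_rows <- records[idx[moved], ]
        child_rows$cb <- child
        child_rows$reads <- take[moved]
        records$reads[idx[moved]] <- records$reads[idx[moved]] - take[moved]
        records <- records[records$reads > 0, ]
        records <- bind_rows(records, child_rows)
        cb_error_rows <- bind_rows(cb_error_rows, tibble(child = child, parent = p))
      }
    }
  }

  records <- aggregate_records(records)
  cells <- tibble(
    cb = c(real_cbs, bg_cbs),
    type = c(rep("real", cfg$n_cells), rep("background", cfg$n_background)),
    damaged = c(damaged, rep(FALSE, cfg$n_background)),
    species = c(species_of_cell, rep(NA_character_, cfg$n_background))
  )
  list(
    records = records,
    truth = list(
      molecules = molecules %>% select("cb", "gene", "umi", "reads"),
      umi_errors = umi_error_rows %||%
        tibble(cb = character(), gene = character(), parent_umi = character(),
               error_umi = character(), position = integer(), reads = integer()),
      cb_errors = cb_error_rows %||% tibble(child = character(), parent = character()),
      cells = cells,
      species_of_gene = species_of_gene,
      mito_genes = mito_genes,
      pool = pool
    ),
    config = cfg
  )
}

# Distinct record keys that exist only because of injected errors.
true_error_keys <- function(truth) {
  err <- truth$umi_errors
  if (nrow(err) == 0) return(character())
  err_keys <- unique(paste(err$cb, err$gene, err$error_umi, sep = "\r"))
  true_keys <- unique(paste(truth$molecules$cb, truth$molecules$gene,
                            truth$molecules$umi, sep = "\r"))
  setdiff(err_keys, true_keys)
}

#' Evaluate a corrected dataset against the generator's ground truth
#'
#' @param original Records as generated (pre-correction).
#' @param corrected Records after UMI error correction.
#' @param truth The `truth` element from [simulate_dataset()].
#' @return A tibble: precision, recall, f1 (of erroneous-UMI removal),
#'   count_rmse (per cell-gene molecule counts vs. truth).
#' @export
evaluate_against_truth <- function(original, corrected, truth) {
  key <- function(r) paste(r$cb, r$gene, r$umi, sep = "\r")
  removed <- setdiff(key(original), key(corrected))
  errors <- true_error_keys(truth)
  tp <- length(intersect(removed, errors))
  precision <- if (length(removed) > 0) tp / length(removed) else 1
  recall <- if (length(errors) > 0) tp / length(errors) else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  true_counts <- truth$molecules %>% count(.data$cb, .data$gene, name = "truth")
  est_counts <- corrected %>%
    filter(!.data$intergenic) %>%
    count(.data$cb, .data$gene, name = "estimate")
  j <- true_counts %>%
    left_join(est_counts, by = c("cb", "gene")) %>%
    mutate(estimate = ifelse(is.na(.data$estimate), 0, .data$estimate))
  tibble(
    precision = precision, recall = recall, f1 = f1,
    count_rmse = sqrt(mean((j$estimate - j$truth)^2))
  )
}

#' Generate synthetic per-cell quality features with noisy labels
#'
#' Two well-separated Gaussian classes in the technical feature space
#' (healthy: low mitochondrial fraction, high reads per UMI; damaged: the
#' opposite), with a chosen fraction of symmetric label noise — the
#' training regime the noise-tolerant classifier must handle.
#'
#' @param n_per_class Cells per class.
#' @param label_noise Fraction of labels flipped in each class.
#' @param separation Distance between class centres in feature units.
#' @param seed Random seed.
#' @return A list: `features` tibble (cb + feature columns), `labels`
#'   tibble (cb, label with noise applied), `true_labels` tibble.
#' @export
simulate_quality_features <- function(n_per_class = 300, label_noise = 0.1,
                                      separation = 4, seed = 1L) {
  set.seed(seed)
  n <- 2 * n_per_class
  truth <- rep(c("high", "low"), each = n_per_class)
  s <- separation
  center <- function(cls) {
    if (cls == "high") c(0.03, 4 + s * 0.5, 1.6, 0.55, 0.02)
    else c(0.03 + s * 0.06, 4 - s * 0.25, 1.6 - s * 0.08, 0.55 + s * 0.05, 0.02 + s * 0.02)
  }
  sds <- c(0.015, 0.5, 0.12, 0.05, 0.01)
  feats <- t(vapply(truth, function(cls) {
    pmax(center(cls) + rnorm(5, 0, sds), c(0, 1, 1, 0, 0))
  }, numeric(5)))
  colnames(feats) <- c("mito_fraction", "reads_per_umi", "umis_per_gene",
                       "low_exp_fraction", "intergenic_fraction")
  cb <- sprintf("cell%04d", seq_len(n))
  labels <- truth
  flip <- c(sample(n_per_class, round(label_noise * n_per_class)),
            n_per_class + sample(n_per_class, round(label_noise * n_per_class)))
  labels[flip] <- ifelse(truth[flip] == "high", "low", "high")
  list(
    features = as_tibble(cbind(tibble(cb = cb, size = 1000), as_tibble(feats))),
    labels = tibble(cb = cb, label = labels),
    true_labels = tibble(cb = cb, label = truth)
  )
}
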