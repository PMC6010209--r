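# Classification of damaged / low-quality cells.
#
# True quality labels are unavailable, but very large barcodes are mostly
# real cells and very small barcodes mostly background, so a noisy training
# set can be built from the barcode-rank curve: on log(size) vs log(rank)
# the curve has a concave head, a linear middle and a convex tail. Cells
# above the linear part seed the high-quality class, cells below it the
# low-quality class, and a classifier tolerant to label noise (a Gaussian
# KDE posterior on three sparse robust principal components of technical
# features) scores every cell.

#' Locate the linear region of the barcode rank curve
#'
#' Fits a smoothing spline to log(size) vs log(rank) (rank 1 = largest) and
#' classifies curvature with a near-zero band of `band_fraction` of the
#' maximum absolute second derivative. `t_U` is the size where the
#' curvature first enters the band (end of the concave head); `t_L` is the
#' size at the last rank before the curvature turns positive (start of the
#' convex tail).
#'
#' @param sizes Per-barcode molecule counts (>= 100 barcodes).
#' @param band_fraction Near-zero band width as a fraction of max |curvature|.
#' @param df Degrees of freedom of the smoothing spline (stiff by default:
#'   the canonical rank curve has a single knee).
#' @param min_curvature Absolute curvature below which the curve is treated
#'   as structureless (straight line: no knee to locate).
#' @return A tibble with columns `t_l` and `t_u` (molecule counts).
#' @export
size_thresholds <- function(sizes, band_fraction = 0.1, df = 6,
                            min_curvature = 0.05) {
  sizes <- sort(sizes[sizes > 0], decreasing = TRUE)
  if (length(sizes) < 100) abort("size_thresholds() needs at least 100 barcodes")
  lr <- log(seq_along(sizes))
  ls <- log(sizes)
  fit <- smooth.spline(lr, ls, df = df)
  grid <- seq(min(lr), max(lr), length.out = 256)
  curv <- predict(fit, grid, deriv = 2)$y
  if (max(abs(curv)) < min_curvature) {
    abort("barcode rank curve has no curvature structure (no knee); supply manual thresholds")
  }
  band <- band_fraction * max(abs(curv))
  i_neg <- which.min(curv)
  if (curv[i_neg] > -band) {
    abort("rank curve lacks a concave head; supply manual thresholds")
  }
  after <- seq(i_neg, length(grid))
  flat <- after[curv[after] > -band]
  if (length(flat) == 0) {
    abort("no linear region found after the knee; supply manual thresholds")
  }
  first_flat <- flat[1]
  pos_after <- which(curv > band & seq_along(curv) > first_flat)
  last_linear <- if (length(pos_after) == 0) length(grid) else max(first_flat, min(pos_after) - 1L)
  # read sizes off the fitted curve: across a near-vertical knee the spline
  # interpolates the gap instead of snapping to one population's edge
  size_at <- function(g) exp(predict(fit, grid[g])$y)
  t_u <- size_at(first_flat)
  t_l <- size_at(last_linear)
  if (t_l > t_u) {
    tmp <- t_l; t_l <- t_u; t_u <- tmp
  }
  tibble(t_l = t_l, t_u = t_u)
}

#' Assign initial quality labels from cell sizes
#'
#' Cells below `t_l` are labelled low-quality; the largest 75% of cells
#' above `t_u` are labelled high-quality; everything else (including the
#' smallest quarter above `t_u`) is unknown.
#'
#' @param sizes Named numeric vector of per-cell molecule counts (names =
#'   barcodes) or a tibble with columns `cb` and `size`.
#' @param thresholds Output of [size_thresholds()] (columns `t_l`, `t_u`).
#' @param top_fraction Fraction of above-threshold cells labelled high.
#' @return A tibble: cb, size, label in {"high", "low", "unknown"}.
#' @export
initial_labels <- function(sizes, thresholds, top_fraction = 0.75) {
  if (is.data.frame(sizes)) sizes <- setNames(sizes$size, sizes$cb)
  lab <- tibble(cb = names(sizes), size = unname(sizes), label = "unknown")
  lab$label[lab$size < thresholds$t_l] <- "low"
  above <- which(lab$size > thresholds$t_u)
  if (length(above) > 0) {
    n_high <- floor(top_fraction * length(above))
    top <- above[order(-lab$size[above], lab$cb[above])][seq_len(n_high)]
    lab$label[top] <- "high"
  }
  if (!any(lab$label == "high")) {
    abort("no cells labelled high-quality; check thresholds")
  }
  lab
}

#' Extract per-cell technical features
#'
#' Computes, per cell: mitochondrial UMI fraction, mean reads per UMI, mean
#' UMIs per gene, fraction of expressed genes with exactly one molecule and
#' fraction of intergenic reads. An optional externally supplied unaligned
#' read fraction can be joined by the caller.
#'
#' @param records A molecule record tibble (post correction).
#' @param mito_genes Character vector of mitochondrial gene identifiers.
#' @return A tibble with one row per cell: cb, size, and the feature
#'   columns.
#' @export
extract_features <- function(records, mito_genes = character()) {
  if (length(mito_genes) == 0) {
    warn("no mitochondrial gene list supplied; mito fraction set to 0")
  }
  genic <- records[!records$intergenic, , drop = FALSE]
  per_cell <- genic %>%
    group_by(.data$cb) %>%
    summarise(
      size = n(),
      mito_fraction = if (length(mito_genes) > 0) mean(.data$gene %in% mito_genes) else 0,
      reads_per_umi = sum(.data$reads) / n(),
      umis_per_gene = n() / dplyr::n_distinct(.data$gene),
      .groups = "drop"
    )
  low_expr <- genic %>%
    count(.data$cb, .data$gene, name = "molecules") %>%
    group_by(.data$cb) %>%
    summarise(low_exp_fraction = mean(.data$molecules == 1), .groups = "drop")
  inter <- records %>%
    group_by(.data$cb) %>%
    summarise(
      intergenic_fraction = sum(.data$reads[.data$intergenic]) / sum(.data$reads),
      .groups = "drop"
    )
  per_cell %>%
    left_join(low_expr, by = "cb") %>%
    left_join(inter, by = "cb")
}

#' Threshold flagging extreme mitochondrial / intergenic fractions
#'
#' m + 4a, where m is the 20% trimmed mean and a the median absolute
#' deviation of the supplied fractions.
#'
#' @param values Numeric vector of fractions (>= 10 values).
#' @return The threshold.
#' @export
extreme_fraction_threshold <- function(values) {
  if (length(values) < 10) abort("need at least 10 values")
  mean(values, trim = 0.2) + 4 * mad(values)
}

# ---------------------------------------------------------------------------
# Sparse robust PCA (grid projection pursuit)
#
# Components maximise the MAD of the projected data, penalised by the L1
# norm of the loadings (lambda = 1 by default; loadings are unit vectors so
# the penalty is zero only for axis-aligned directions). Directions are
# found by cyclic plane rotations over an angle grid — deterministic and
# outlier-resistant — and the data are deflated between components.

sparse_robust_pca <- function(x, n_components = 3, lambda = 1,
                              n_angles = 90, n_sweeps = 10) {
  d <- ncol(x)
  n_components <- min(n_components, d)
  scale_ref <- median(apply(x, 2, mad))
  if (scale_ref == 0) scale_ref <- 1
  objective <- function(a) {
    s <- mad(x %*% a)
    s^2 - lambda * scale_ref^2 * (sum(abs(a)) - 1)
  }
  loadings <- matrix(0, d, n_components)
  basis <- diag(d)  # orthonormal basis of the current residual space
  for (comp in seq_len(n_components)) {
    db <- ncol(basis)
    proj <- x %*% basis
    col_scales <- apply(proj, 2, mad)
    a <- rep(0, db)
    a[which.max(col_scales)] <- 1
    obj_proj <- function(v) objective(basis %*% v)
    angles <- seq(-pi / 2, pi / 2, length.out = n_angles)
    for (sweep in seq_len(n_sweeps)) {
      improved <- FALSE
      for (j in seq_len(db)) {
        e <- rep(0, db); e[j] <- 1
        if (abs(sum(a * e)) > 1 - 1e-12) next
        # orthonormalize e against a within the plane
        e <- e - sum(a * e) * a
        e <- e / sqrt(sum(e^2))
        vals <- vapply(angles, function(th) obj_proj(cos(th) * a + sin(th) * e), numeric(1))
        best <- which.max(vals)
        if (vals[best] > obj_proj(a) + 1e-12) {
          a <- cos(angles[best]) * a + sin(angles[best]) * e
          a <- a / sqrt(sum(a^2))
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    v <- basis %*% a
    # sparsify: zero out negligible loadings and renormalize
    v[abs(v) < 1e-8] <- 0
    v <- v / sqrt(sum(v^2))
    loadings[, comp] <- v
    if (comp < n_components) {
      # deflate: orthonormal basis of the complement of v within basis
      b <- basis - v %*% (t(v) %*% basis)
      qr_b <- qr(b)
      basis <- qr.Q(qr_b)[, seq_len(qr_b$rank), drop = FALSE]
    }
  }
  rownames(loadings) <- colnames(x)
  loadings
}

# ---------------------------------------------------------------------------
# Gaussian KDE with the normal-scale bandwidth

# Normal-scale plug-in bandwidth matrix for d-variate data:
# H = (4 / (d + 2))^(2/(d+4)) n^(-2/(d+4)) * Sigma_hat.
normal_scale_bandwidth <- function(x) {
  n <- nrow(x)
  d <- ncol(x)
  (4 / (d + 2))^(2 / (d + 4)) * n^(-2 / (d + 4)) * cov(x)
}

kde_fit <- function(x) {
  H <- normal_scale_bandwidth(x)
  # guard against degenerate covariance
  H <- H + diag(1e-10, ncol(x))
  list(x = x, H = H, Hinv = solve(H), logdet = determinant(H)$modulus[1])
}

kde_density <- function(fit, newx) {
  n <- nrow(fit$x)
  d <- ncol(fit$x)
  const <- -0.5 * (d * log(2 * pi) + fit$logdet)
  out <- numeric(nrow(newx))
  for (i in seq_len(nrow(newx))) {
    diff <- sweep(fit$x, 2, newx[i, ])
    md <- rowSums((diff %*% fit$Hinv) * diff)
    out[i] <- mean(exp(const - 0.5 * md))
  }
  out
}

# ---------------------------------------------------------------------------
# Classifier

quality_feature_columns <- function(features) {
  cols <- c("mito_fraction", "reads_per_umi", "umis_per_gene",
            "low_exp_fraction", "intergenic_fraction", "unaligned_fraction")
  intersect(cols, names(features))
}

#' Train the noise-tolerant cell-quality classifier
#'
#' Standardizes the features (median / MAD), fits a three-component sparse
#' robust PCA (lambda = 1), decides whether extreme mitochondrial /
#' intergenic fractions should be relabelled before training (when either
#' fraction carries >= 5% of the absolute loading on any component) or
#' filtered after scoring, and fits one normal-scale-bandwidth Gaussian KDE
#' per class on the component scores. Scores are the posterior of the
#' high-quality class under equal priors.
#'
#' @param features Feature tibble from [extract_features()].
#' @param labels Label tibble from [initial_labels()] (columns cb, label).
#' @param lambda Sparsity level of the robust PCA.
#' @param priors Length-2 class priors (high, low).
#' @return An object of class `quality_classifier`.
#' @export
train_quality_classifier <- function(features, labels, lambda = 1,
                                     priors = c(0.5, 0.5)) {
  cols <- quality_feature_columns(features)
  df <- features %>% left_join(labels %>% select("cb", "label"), by = "cb")
  df$label[is.na(df$label)] <- "unknown"

  # extreme-fraction thresholds across the whole dataset
  # a zero MAD (e.g. most barcodes carry no mitochondrial molecule) makes
  # the m + 4a rule degenerate — over half the data would be "extreme"
  extremes <- list()
  for (fc in intersect(c("mito_fraction", "intergenic_fraction"), cols)) {
    vals <- features[[fc]]
    if (length(vals) >= 10 && mad(vals) > 0) {
      extremes[[fc]] <- extreme_fraction_threshold(vals)
    }
  }

  centers <- vapply(cols, function(c) median(features[[c]]), numeric(1))
  scales <- vapply(cols, function(c) {
    s <- mad(features[[c]])
    if (s == 0) s <- sd(features[[c]])
    if (is.na(s) || s == 0) s <- 1
    s
  }, numeric(1))
  standardize <- function(f) {
    m <- as.matrix(f[, cols])
    sweep(sweep(m, 2, centers), 2, scales, "/")
  }

  train <- df[df$label %in% c("high", "low"), , drop = FALSE]
  if (sum(train$label == "high") < 20 || sum(train$label == "low") < 20) {
    abort("both classes need at least 20 labelled cells")
  }
  loadings <- sparse_robust_pca(standardize(train), n_components = 3,
                                lambda = lambda)

  # pre- vs post-training handling of extreme fractions
  pre_label <- logical(0)
  for (fc in names(extremes)) {
    load_share <- abs(loadings[fc, ]) / colSums(abs(loadings))
    pre_label[fc] <- any(load_share >= 0.05)
  }
  if (any(pre_label)) {
    for (fc in names(which(pre_label))) {
      extreme_cells <- features$cb[features[[fc]] > extremes[[fc]]]
      train$label[train$cb %in% extreme_cells] <- "low"
    }
    if (sum(train$label == "high") < 20) {
      abort("extreme-fraction relabelling removed the high class")
    }
    loadings <- sparse_robust_pca(standardize(train), n_components = 3,
                                  lambda = lambda)
  }

  scores_train <- standardize(train) %*% loadings
  kde_high <- kde_fit(scores_train[train$label == "high", , drop = FALSE])
  kde_low <- kde_fit(scores_train[train$label == "low", , drop = FALSE])

  structure(
    list(
      feature_columns = cols,
      centers = centers, scales = scales,
      loadings = loadings,
      kde_high = kde_high, kde_low = kde_low,
      priors = priors / sum(priors),
      extremes = extremes,
      pre_label = pre_label
    ),
    class = "quality_classifier"
  )
}

#' @export
print.quality_classifier <- function(x, ...) {
  cat(sprintf(
    "<quality_classifier> %d features -> 3 robust sparse PCs, KDE n = %d/%d (high/low)\n",
    length(x$feature_columns), nrow(x$kde_high$x), nrow(x$kde_low$x)
  ))
  invisible(x)
}

#' Score cells with a trained quality classifier
#'
#' @param clf A `quality_classifier`.
#' @param features Feature tibble (same columns as in training).
#' @return A tibble: cb, score in `[0, 1]` (posterior probability of high
#'   quality). Cells exceeding an extreme-fraction threshold handled in
#'   post mode are forced to score 0.
#' @export
score_cells <- function(clf, features) {
  m <- as.matrix(features[, clf$feature_columns])
  m <- sweep(sweep(m, 2, clf$centers), 2, clf$scales, "/")
  pcs <- m %*% clf$loadings
  dh <- kde_density(clf$kde_high, pcs) * clf$priors[1]
  dl <- kde_density(clf$kde_low, pcs) * clf$priors[2]
  tot <- dh + dl
  score <- ifelse(tot > 0, dh / tot, 0.5)
  post_cols <- names(clf$pre_label)[!clf$pre_label]
  for (fc in post_cols) {
    score[features[[fc]] > clf$extremes[[fc]]] <- 0
  }
  tibble(cb = features$cb, score = pmin(pmax(score, 0), 1))
}

#' Select cells to keep from sizes and quality scores
#'
#' Cells above the upper size threshold are kept unless their score is
#' below `drop_lo` (filtered); cells below it are kept only when their
#' score exceeds `keep_hi` (rescued). All kept cells must express at least
#' `min_genes` genes.
#'
#' @param scores Tibble from [score_cells()].
#' @param sizes Named molecule counts per cell.
#' @param thresholds Output of [size_thresholds()].
#' @param keep_hi Rescue threshold for small cells.
#' @param drop_lo Filtering threshold for large cells.
#' @param genes_per_cell Named count of expressed genes per cell.
#' @param min_genes Minimal expressed genes.
#' @return A tibble: cb, size, score, status in
#'   {"kept", "rescued", "filtered"} and `kept` logical.
#' @export
filter_cells <- function(scores, sizes, thresholds, keep_hi = 0.9,
                         drop_lo = 0.1, genes_per_cell = NULL, min_genes = 0) {
  out <- scores %>%
    mutate(size = unname(sizes[.data$cb]))
  big <- out$size >= thresholds$t_u
  status <- ifelse(
    big,
    ifelse(out$score >= drop_lo, "kept", "filtered"),
    ifelse(out$score > keep_hi, "rescued", "filtered")
  )
  if (!is.null(genes_per_cell) && min_genes > 0) {
    status[unname(genes_per_cell[out$cb]) < min_genes] <- "filtered"
  }
  out %>% mutate(status = status, kept = status != "filtered")
}
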