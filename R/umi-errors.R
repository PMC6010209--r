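# Removal of erroneous UMIs within each gene of each cell.
#
# A single-base sequencing or PCR error turns reads of a true UMI U into a
# spurious UMI u at Hamming distance 1, inflating the molecule count. Three
# published heuristics are provided as baselines:
#   cluster      drop u if an adjacent UMI has >= reads (cluster-neq: >)
#   directional  drop u if an adjacent UMI has more than twice its reads
# plus the package's Bayesian filter, which scores, for every target UMI U,
# the posterior over how many of its lower-read Hamming-1 neighbours are
# errors. The posterior combines four ingredients:
#   * base-call quality of the distinguishing position, via quantized
#     distributions p(q) and p(q | error) trained on genes carrying exactly
#     two adjacent UMIs (those pairs are almost certainly error-generated);
#   * a prior on the number of *real* adjacent UMIs, from a dynamic program
#     over the process of drawing S_g UMIs from the pool, indexed by the
#     probability mass adjacent to U and quantized in steps of dp_step;
#   * a binomial model for the total number of erroneous reads, with
#     per-read error rate p_E estimated on the same training pairs;
#   * an occupancy correction for error events that collide on the same
#     erroneous sequence (the same dynamic program with adjacency mass 1).

# ---------------------------------------------------------------------------
# Gene/cell UMI groups and neighbourhoods

# Split records into per-(cb, gene) groups. Returns a list of lists with
# character umis, numeric reads and a list of quality vectors.
umi_groups <- function(records, min_umis = 1L) {
  key <- paste(records$cb, records$gene, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  idx <- idx[lengths(idx) >= min_umis]
  lapply(idx, function(i) {
    list(
      cb = records$cb[i[1]], gene = records$gene[i[1]],
      umis = records$umi[i], reads = records$reads[i],
      quals = records$quals[i]
    )
  })
}

#' Hamming-1 neighbourhood of a UMI within its gene group
#'
#' Splits the adjacent UMIs of `u` into the small side (reads <= reads of
#' `u`; ties count as small) and the large side, the unit on which the
#' Bayesian posterior operates.
#'
#' @param u Target UMI sequence (must be present in the group).
#' @param group A tibble or list with elements/columns `umis`, `reads`,
#'   `quals` describing one gene in one cell.
#' @return A list of class `umi_neighborhood`: target `umi`, `reads`,
#'   tibble `omega` (columns umi, reads, q = neighbour's mean quality at the
#'   distinguishing position, side), counts `n_s` and `n_l`.
#' @export
adjacent_umis <- function(u, group) {
  pos <- match(u, group$umis)
  if (is.na(pos)) abort(sprintf("UMI %s is not present in the group", u))
  R <- group$reads[pos]
  nb <- hamming1_neighbors(u)
  hit <- match(nb, group$umis)
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) {
    omega <- tibble(umi = character(), reads = numeric(), q = numeric(), side = character())
  } else {
    q <- vapply(hit, function(i) {
      group$quals[[i]][mismatch_position(u, group$umis[i])]
    }, numeric(1))
    omega <- tibble(
      umi = group$umis[hit],
      reads = group$reads[hit],
      q = q,
      side = ifelse(group$reads[hit] <= R, "small", "large")
    )
  }
  structure(
    list(
      umi = u, reads = R, omega = omega,
      n_s = sum(omega$side == "small"), n_l = sum(omega$side == "large")
    ),
    class = "umi_neighborhood"
  )
}

# ---------------------------------------------------------------------------
# Baseline filters

# Hamming-1 adjacency lists for a group (index -> integer vector of
# adjacent indices), computed from one vectorized distance matrix.
adjacency_lists <- function(umis) {
  hm <- hamming_matrix(umis)
  lapply(seq_along(umis), function(i) which(hm[i, ] == 1L))
}

# Kept-set computation for one group under the cluster rule.
cluster_kept <- function(umis, reads, neq = FALSE, adj = NULL) {
  if (is.null(adj)) adj <- adjacency_lists(umis)
  keep <- rep(TRUE, length(umis))
  for (i in seq_along(umis)) {
    nb <- adj[[i]]
    if (length(nb) == 0) next
    if (neq) {
      keep[i] <- !any(reads[nb] > reads[i])
    } else {
      # ties resolved deterministically: the lexicographically smaller UMI wins
      dominates <- reads[nb] > reads[i] |
        (reads[nb] == reads[i] & umis[nb] < umis[i])
      keep[i] <- !any(dominates)
    }
  }
  keep
}

# Kept-set computation under the directional rule: a UMI is erroneous if any
# adjacent UMI has more than `ratio` times its reads. Evaluated on the
# original read counts, which equals the fixpoint of transitive absorption
# along the directed adjacency network.
directional_kept <- function(umis, reads, ratio = 2, adj = NULL) {
  if (is.null(adj)) adj <- adjacency_lists(umis)
  keep <- rep(TRUE, length(umis))
  for (i in seq_along(umis)) {
    nb <- adj[[i]]
    if (length(nb) > 0 && any(reads[nb] > ratio * reads[i])) keep[i] <- FALSE
  }
  keep
}

#' Cluster baseline filter for one UMI group
#'
#' @param group List/tibble with `umis` and `reads`.
#' @param neq If `TRUE`, only strictly larger adjacent UMIs dominate
#'   (the cluster-neq variant); otherwise ties are broken in favour of the
#'   lexicographically smaller UMI.
#' @return Character vector of kept UMIs.
#' @export
cluster_filter <- function(group, neq = FALSE) {
  group$umis[cluster_kept(group$umis, group$reads, neq = neq)]
}

#' Directional baseline filter for one UMI group
#'
#' @param group List/tibble with `umis` and `reads`.
#' @param ratio Read-count ratio above which an adjacent UMI absorbs this one.
#' @return Character vector of kept UMIs.
#' @export
directional_filter <- function(group, ratio = 2) {
  group$umis[directional_kept(group$umis, group$reads, ratio = ratio)]
}

# Reassign reads of dropped UMIs to retained ones: each dropped UMI routes to
# its largest-read Hamming-1 neighbour (ties lexicographic), chains resolved
# to a kept endpoint. Returns integer target index per dropped UMI.
resolve_targets <- function(umis, reads, keep, adj = NULL) {
  if (is.null(adj)) adj <- adjacency_lists(umis)
  n <- length(umis)
  first_hop <- integer(n)
  for (i in which(!keep)) {
    nb <- adj[[i]]
    if (length(nb) == 0) {
      first_hop[i] <- i  # no neighbour: keep in place (cannot happen for drops)
      next
    }
    ord <- nb[order(-reads[nb], umis[nb])]
    first_hop[i] <- ord[1]
  }
  target <- integer(n)
  for (i in which(!keep)) {
    t <- first_hop[i]
    seen <- i
    while (!keep[t] && !(t %in% seen) && first_hop[t] != t) {
      seen <- c(seen, t)
      t <- first_hop[t]
    }
    target[i] <- t
  }
  target
}

# ---------------------------------------------------------------------------
# Quality model

#' Train the base-call quality model for the Bayesian filter
#'
#' The marginal p(q) pools the distinguishing-position mean qualities of all
#' Hamming-1 adjacent UMI pairs in the dataset and quantizes them to at most
#' `k_q` support points (uniform quantiles; near-duplicate quantiles merged;
#' every q rounded to the nearest support point). The error conditional
#' p(q | error) and the per-read error rate p_E are estimated from genes
#' containing exactly two UMIs that are Hamming-1 adjacent: the smaller UMI
#' of such a pair is almost certainly an error copy of the larger.
#'
#' @param records A molecule record tibble.
#' @param k_q Number of quality quantiles (default 15).
#' @param pseudocount Regularization added per support point when estimating
#'   p(q | error), so that no quality value has exactly zero error mass.
#' @return An object of class `umi_quality_model`: `support`, `p_q`,
#'   `p_q_err`, `p_e`, `n_training_pairs`.
#' @export
train_quality_model <- function(records, k_q = 15, pseudocount = 0.5) {
  groups <- umi_groups(records, min_umis = 2L)
  all_q <- numeric(0)
  err_q <- numeric(0)
  err_r <- numeric(0)
  err_R <- numeric(0)
  for (g in groups) {
    hm <- hamming_matrix(g$umis)
    pairs <- which(hm == 1L & upper.tri(hm), arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      pos <- mismatch_position(g$umis[i], g$umis[j])
      all_q <- c(all_q, g$quals[[i]][pos], g$quals[[j]][pos])
      if (length(g$umis) == 2L) {
        small <- if (g$reads[i] < g$reads[j]) i else if (g$reads[j] < g$reads[i]) j else {
          if (g$umis[i] > g$umis[j]) i else j
        }
        big <- setdiff(c(i, j), small)
        err_q <- c(err_q, g$quals[[small]][pos])
        err_r <- c(err_r, g$reads[small])
        err_R <- c(err_R, g$reads[big])
      }
    }
  }
  if (length(err_q) == 0) {
    abort(paste(
      "no training pairs: the dataset has no gene with exactly two",
      "Hamming-1 adjacent UMIs; fall back to the cluster method"
    ))
  }
  support <- quantize_support(all_q, k_q)
  q_all_r <- round_to_support(all_q, support)
  q_err_r <- round_to_support(err_q, support)
  p_q <- tabulate(match(q_all_r, support), nbins = length(support))
  p_q <- p_q / sum(p_q)
  p_q_err <- tabulate(match(q_err_r, support), nbins = length(support)) + pseudocount
  p_q_err <- p_q_err / sum(p_q_err)
  structure(
    list(
      support = support, p_q = p_q, p_q_err = p_q_err,
      p_e = sum(err_r) / sum(err_r + err_R),
      n_training_pairs = length(err_q)
    ),
    class = "umi_quality_model"
  )
}

# k uniformly spaced quantiles, merged when closer than 1e-5.
quantize_support <- function(values, k) {
  if (k < 1) abort("k_q must be >= 1")
  if (k == 1) return(median(values))
  qs <- unname(quantile(values, probs = seq(0, 1, length.out = k), type = 7))
  keep <- c(TRUE, diff(qs) >= 1e-5)
  qs[keep]
}

round_to_support <- function(values, support) {
  idx <- vapply(values, function(v) which.min(abs(support - v)), integer(1))
  support[idx]
}

# Per-value lookup of p(q) and p(q|Err) after rounding to the support.
quality_probs <- function(qm, q) {
  idx <- vapply(q, function(v) which.min(abs(qm$support - v)), integer(1))
  list(p_q = qm$p_q[idx], p_q_err = qm$p_q_err[idx])
}

#' @export
print.umi_quality_model <- function(x, ...) {
  cat(sprintf(
    "<umi_quality_model> %d support points, p_E = %.4f, %d training pairs\n",
    length(x$support), x$p_e, x$n_training_pairs
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Adjacency prior (dynamic program)

#' Build the adjacency-count prior cache
#'
#' For a UMI U with adjacency probability mass p (the summed pool
#' probability of its 3L Hamming-1 variants), the number N' of distinct
#' *real* adjacent UMIs after s molecules are drawn follows a Markov chain:
#' from state k, a draw lands on a new adjacent sequence with probability
#' p(K-k)/K (K = 3L possible adjacent sequences) and otherwise leaves k
#' unchanged. The chain is tabulated by dynamic programming for every
#' quantized value of p (step `dp_step`), columns indexed by the number of
#' picks s = 0..S_max; tables are built lazily and cached.
#'
#' @param S_max Largest number of picks needed (max gene group size).
#' @param L UMI length (K = 3L).
#' @param dp_step Quantization step for the adjacency probability.
#' @return An object of class `adjacency_prior` (environment-backed cache).
#' @export
build_adjacency_prior <- function(S_max, L, dp_step = 0.01) {
  env <- new.env(parent = emptyenv())
  env$tables <- vector("list", as.integer(ceiling(1 / dp_step)))
  structure(
    list(K = 3L * as.integer(L), S_max = as.integer(S_max),
         dp_step = dp_step, cache = env),
    class = "adjacency_prior"
  )
}

# DP table for one adjacency probability: (K+1) x (S_max+1) matrix, rows
# k = 0..K, columns s = 0..S_max picks.
adjacency_dp_table <- function(K, S_max, p) {
  t <- matrix(0, nrow = K + 1, ncol = S_max + 1)
  t[1, 1] <- 1
  ks <- 0:K
  stay <- 1 - p * (K - ks) / K          # remain at k
  gain <- p * (K - ks + 1) / K          # arrive at k from k-1
  for (s in seq_len(S_max)) {
    col <- t[, s]
    t[, s + 1] <- col * stay + c(0, col[-(K + 1)] * gain[-1])
  }
  t
}

# Quantized bin index for an adjacency probability; probability 0 maps to
# the smallest bin.
quantize_p_bin <- function(prior, p) {
  nb <- length(prior$cache$tables)
  min(max(1L, as.integer(ceiling(p / prior$dp_step))), nb)
}

#' Look up the cached DP table for an adjacency probability
#'
#' @param prior An `adjacency_prior`.
#' @param p Adjacency probability in `[0, 1]` (quantized to the cache grid).
#' @return Matrix of p(N' = k | s picks), rows k = 0..K, columns s = 0..S_max.
#' @export
prior_table <- function(prior, p) {
  bin <- quantize_p_bin(prior, p)
  tab <- prior$cache$tables[[bin]]
  if (is.null(tab)) {
    tab <- adjacency_dp_table(prior$K, prior$S_max, bin * prior$dp_step)
    prior$cache$tables[[bin]] <- tab
  }
  tab
}

#' Posterior over the number of real UMIs among the small-side neighbours
#'
#' Reads p(N' = n + N_L | S_g - 1 picks) from the adjacency prior —
#' conditioning the tail of N' on N' >= N_L as the model prescribes reduces,
#' after differencing and renormalization over the support 0..N_S, to this
#' slice — and renormalizes.
#'
#' @param n_s,n_l Small- and large-side adjacent UMI counts.
#' @param s_g Number of UMIs in the gene group (including the target).
#' @param p_adj Adjacency probability mass of the target UMI.
#' @param prior An `adjacency_prior`.
#' @return Numeric vector of probabilities for #Real = 0..n_s.
#' @export
real_count_distribution <- function(n_s, n_l, s_g, p_adj, prior) {
  if (n_s == 0) return(1)
  picks <- min(s_g - 1L, prior$S_max)
  tab <- prior_table(prior, p_adj)
  idx <- n_l + 0:n_s  # N' values
  mass <- ifelse(idx <= prior$K, tab[pmin(idx, prior$K) + 1, picks + 1], 0)
  if (sum(mass) <= 0) {
    # degenerate corner (N_L beyond the tabulated range): all-real fallback
    mass <- c(rep(0, n_s), 1)
  }
  mass / sum(mass)
}

#' Distribution of the total number of erroneous UMIs
#'
#' Error reads accumulate at a constant per-read rate p_E, so the total
#' erroneous read count r_E out of R + r_E reads is modelled binomially.
#' For i candidate errors (in search order) the weight is the binomial mass
#' at the cumulative read count of the first i candidates; weights are
#' normalized over i = 0..N_S.
#'
#' @param ordered_reads Read counts of the small-side candidates in search
#'   order (most error-like first).
#' @param R Read count of the target UMI.
#' @param p_e Per-read error rate in (0, 1).
#' @return Numeric vector of probabilities for #Errors_T = 0..N_S.
#' @export
error_count_distribution <- function(ordered_reads, R, p_e) {
  if (p_e <= 0 || p_e >= 1) abort("p_e must be in (0, 1)")
  r_cum <- c(0, cumsum(ordered_reads))
  w <- dbinom(r_cum, size = R + r_cum, prob = p_e)
  w / sum(w)
}

#' Probability that error events collide to fewer distinct sequences
#'
#' `total` error events each land uniformly on one of the K adjacent
#' sequences; the chance that exactly `observed` distinct sequences result
#' is the adjacency DP evaluated at adjacency probability 1 after `total`
#' picks.
#'
#' @param observed Number of distinct erroneous UMIs observed.
#' @param total Total number of error events (>= observed).
#' @param prior An `adjacency_prior`.
#' @return Probability.
#' @export
collisions_among_errors <- function(observed, total, prior) {
  if (observed > total) abort("observed errors cannot exceed total errors")
  if (total == 0) return(as.numeric(observed == 0))
  if (total > prior$S_max) total <- prior$S_max
  tab <- prior_table(prior, 1)
  if (observed > prior$K) return(0)
  tab[observed + 1, total + 1]
}

# ---------------------------------------------------------------------------
# Posterior over error counts within a neighbourhood

# Order the small-side candidates: most error-like first (ascending reads,
# then descending error likelihood ratio p(q|Err)/p(q), then sequence).
order_candidates <- function(omega_small, qm) {
  qp <- quality_probs(qm, omega_small$q)
  lr <- ifelse(qp$p_q > 0, qp$p_q_err / qp$p_q, Inf)
  ord <- order(omega_small$reads, -lr, omega_small$umi)
  list(
    omega = omega_small[ord, , drop = FALSE],
    p_q = qp$p_q[ord],
    p_q_err = qp$p_q_err[ord]
  )
}

#' Unnormalized probability of one error/real split of a neighbourhood
#'
#' Multiplies the quality likelihoods of the split, the prior probability of
#' the implied number of real adjacent UMIs, and the collision-corrected
#' probability of the implied number of error events. Exposed mainly for
#' verification against exhaustive enumeration; [posterior_error_count()]
#' computes the same quantity incrementally along the nested search order.
#'
#' @param view A `umi_neighborhood` from [adjacent_umis()].
#' @param error_umis Character vector: the subset of small-side neighbours
#'   declared erroneous.
#' @param qm A `umi_quality_model`.
#' @param prior An `adjacency_prior`.
#' @param s_g Gene group size.
#' @param p_adj Adjacency probability of the target.
#' @return Unnormalized probability.
#' @export
partition_probability <- function(view, error_umis, qm, prior, s_g, p_adj) {
  small <- view$omega[view$omega$side == "small", , drop = FALSE]
  if (!all(error_umis %in% small$umi)) {
    abort("error_umis must be a subset of the small-side neighbours")
  }
  ord <- order_candidates(small, qm)
  n_s <- nrow(small)
  in_err <- ord$omega$umi %in% error_umis
  j <- sum(in_err)
  q_factor <- prod(ord$p_q_err[in_err]) * prod(ord$p_q[!in_err])
  real_dist <- real_count_distribution(n_s, view$n_l, s_g, p_adj, prior)
  err_dist <- error_count_distribution(ord$omega$reads, view$reads, qm$p_e)
  coll <- vapply(j:n_s, function(i) collisions_among_errors(j, i, prior), numeric(1))
  q_factor * real_dist[n_s - j + 1] * sum(coll * err_dist[(j:n_s) + 1])
}

# Vector-level core of the nested-prefix posterior: everything the hot
# loop needs, no data-frame allocation. `tiebreak` orders candidates
# deterministically after reads and quality likelihood ratio.
posterior_nested <- function(reads_small, q_small, tiebreak, n_l, R, s_g,
                             p_adj, qm, prior) {
  n_s <- length(reads_small)
  qi <- vapply(q_small, function(v) which.min(abs(qm$support - v)), integer(1))
  p_q <- qm$p_q[qi]
  p_q_err <- qm$p_q_err[qi]
  lr <- ifelse(p_q > 0, p_q_err / p_q, Inf)
  ord <- order(reads_small, -lr, tiebreak)
  p_q <- p_q[ord]
  p_q_err <- p_q_err[ord]
  real_dist <- real_count_distribution(n_s, n_l, s_g, p_adj, prior)
  err_dist <- error_count_distribution(reads_small[ord], R, qm$p_e)
  coll_tab <- prior_table(prior, 1)
  err_term <- vapply(0:n_s, function(j) {
    if (j > prior$K) return(0)
    is <- j:n_s
    sum(coll_tab[j + 1, pmin(is, prior$S_max) + 1] * err_dist[is + 1])
  }, numeric(1))
  probs <- c(1, cumprod(p_q_err)) *
    rev(c(1, cumprod(rev(p_q)))) *
    rev(real_dist) * err_term
  if (!all(is.finite(probs)) || sum(probs) <= 0) {
    probs <- c(1, rep(0, n_s))  # degenerate neighbourhood: declare no errors
  }
  probs <- probs / sum(probs)
  list(ord = ord, posterior = probs, map = which.max(probs) - 1L)
}

#' Posterior over the number of erroneous neighbours of a target UMI
#'
#' Candidates are the small-side neighbours ordered most-error-like first;
#' only the nested prefixes of this order are scored (the exhaustive search
#' over all subsets collapses onto these prefixes because error probability
#' decays exponentially in read count). Probabilities are normalized over
#' the prefixes.
#'
#' @inheritParams partition_probability
#' @return A list of class `umi_error_posterior`: `candidates` (tibble in
#'   search order), `posterior` (probabilities for #Errors = 0..N_S),
#'   `map` (MAP error count) and `error_umis` (the MAP prefix).
#' @export
posterior_error_count <- function(view, qm, prior, s_g, p_adj) {
  small <- view$omega[view$omega$side == "small", , drop = FALSE]
  n_s <- nrow(small)
  if (n_s == 0) {
    return(structure(
      list(candidates = small, posterior = 1, map = 0L, error_umis = character()),
      class = "umi_error_posterior"
    ))
  }
  res <- posterior_nested(small$reads, small$q, small$umi, view$n_l,
                          view$reads, s_g, p_adj, qm, prior)
  structure(
    list(
      candidates = small[res$ord, , drop = FALSE],
      posterior = res$posterior,
      map = res$map,
      error_umis = small$umi[res$ord][seq_len(res$map)]
    ),
    class = "umi_error_posterior"
  )
}

# ---------------------------------------------------------------------------
# Dataset-level correction

#' Correct UMI sequence errors in a record table
#'
#' Applies the chosen filter within each (cell, gene) group. Reads of
#' removed UMIs are reassigned to the UMI they merge into, so total reads
#' are conserved. The Bayesian method runs iteratively per group until no
#' deletion happens in a full pass (or `max_iterations`).
#'
#' @param records A molecule record tibble.
#' @param method One of `"none"`, `"cluster"`, `"cluster-neq"`,
#'   `"directional"`, `"bayesian"`.
#' @param dist Optional `umi_distribution` (estimated from `records` when
#'   missing; used by the Bayesian method).
#' @param quality_model Optional pre-trained `umi_quality_model`.
#' @param k_quantiles Quality quantization level for training.
#' @param dp_step Adjacency-prior quantization step.
#' @param max_iterations Iteration cap for the Bayesian method.
#' @param directional_ratio Read ratio for the directional baseline.
#' @return The corrected record tibble; the removal audit (one row per
#'   removed UMI: cell, gene, removed_umi, target_umi, posterior, method)
#'   is attached as attribute `"audit"`.
#' @export
correct_umi_errors <- function(records,
                               method = c("bayesian", "cluster", "cluster-neq",
                                          "directional", "none"),
                               dist = NULL,
                               quality_model = NULL,
                               k_quantiles = 15,
                               dp_step = 0.01,
                               max_iterations = 10,
                               directional_ratio = 2) {
  method <- match.arg(method)
  audit0 <- tibble(
    cb = character(), gene = character(), removed_umi = character(),
    target_umi = character(), posterior = numeric(), method = character()
  )
  if (method == "none" || nrow(records) == 0) {
    attr(records, "audit") <- audit0
    return(records)
  }
  groups <- umi_groups(records)
  if (method == "bayesian") {
    if (is.null(dist)) dist <- estimate_umi_distribution(records)
    if (is.null(quality_model)) {
      quality_model <- train_quality_model(records, k_q = k_quantiles)
    }
    s_max <- max(lengths(lapply(groups, `[[`, "umis")))
    prior <- build_adjacency_prior(S_max = s_max, L = umi_length(records),
                                   dp_step = dp_step)
    uu <- unique(records$umi)
    p_adj_map <- vapply(uu, function(u) {
      sum(dist$probs[match(hamming1_neighbors(u), names(dist$probs))], na.rm = TRUE)
    }, numeric(1))
    names(p_adj_map) <- uu
  }
  out_rows <- vector("list", length(groups))
  audit_rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (length(g$umis) < 2) {
      out_rows[[gi]] <- g
      next
    }
    res <- switch(
      method,
      "cluster" = filter_group_simple(g, cluster_kept(g$umis, g$reads, neq = FALSE), method),
      "cluster-neq" = filter_group_simple(g, cluster_kept(g$umis, g$reads, neq = TRUE), method),
      "directional" = filter_group_simple(g, directional_kept(g$umis, g$reads, ratio = directional_ratio), method),
      "bayesian" = filter_group_bayesian(g, dist, quality_model, prior,
                                         p_adj_map,
                                         max_iterations = max_iterations)
    )
    out_rows[[gi]] <- res$group
    audit_rows[[gi]] <- res$audit
  }
  corrected <- groups_to_records(out_rows, intergenic_map(records))
  audit <- bind_rows(c(list(audit0), audit_rows))
  attr(corrected, "audit") <- audit
  corrected
}

intergenic_map <- function(records) {
  m <- records %>% distinct(.data$gene, .data$intergenic)
  setNames(m$intergenic, m$gene)
}

groups_to_records <- function(groups, ig_map) {
  groups <- groups[!vapply(groups, is.null, logical(1))]
  rows <- lapply(groups, function(g) {
    tibble(
      cb = g$cb, umi = g$umis, gene = g$gene, reads = g$reads,
      quals = g$quals, intergenic = unname(ig_map[g$gene])
    )
  })
  out <- bind_rows(rows)
  out[order(out$cb, out$gene, out$umi), ]
}

# Apply a kept mask to a group, reassigning dropped reads.
filter_group_simple <- function(g, keep, method) {
  if (all(keep)) {
    return(list(group = g, audit = NULL))
  }
  target <- resolve_targets(g$umis, g$reads, keep)
  audit <- tibble(
    cb = g$cb, gene = g$gene,
    removed_umi = g$umis[!keep],
    target_umi = g$umis[target[!keep]],
    posterior = NA_real_, method = method
  )
  for (i in which(!keep)) {
    t <- target[i]
    w <- g$reads[c(t, i)]
    g$quals[[t]] <- (g$quals[[t]] * w[1] + g$quals[[i]] * w[2]) / sum(w)
    g$reads[t] <- sum(w)
  }
  g$umis <- g$umis[keep]
  g$reads <- g$reads[keep]
  g$quals <- g$quals[keep]
  list(group = g, audit = audit)
}

# Iterative Bayesian correction of one group. p_adj_map is a named vector
# of per-UMI adjacency probability mass precomputed from the empirical
# distribution.
filter_group_bayesian <- function(g, dist, qm, prior, p_adj_map,
                                  max_iterations = 10) {
  a_removed <- character(0)
  a_target <- character(0)
  a_post <- numeric(0)
  for (iter in seq_len(max_iterations)) {
    changed <- FALSE
    hm <- hamming_matrix(g$umis)
    alive <- rep(TRUE, length(g$umis))
    ord <- order(-g$reads, g$umis)
    for (oi in ord) {
      if (!alive[oi]) next
      nb <- which(hm[oi, ] == 1L & alive)
      if (length(nb) == 0) next
      R <- g$reads[oi]
      small <- nb[g$reads[nb] <= R]
      if (length(small) == 0) next
      n_l <- length(nb) - length(small)
      q <- vapply(small, function(j) {
        g$quals[[j]][mismatch_position(g$umis[oi], g$umis[j])]
      }, numeric(1))
      res <- posterior_nested(g$reads[small], q, g$umis[small], n_l, R,
                              s_g = sum(alive),
                              p_adj = p_adj_map[[g$umis[oi]]],
                              qm = qm, prior = prior)
      if (res$map == 0) next
      changed <- TRUE
      drop_idx <- small[res$ord][seq_len(res$map)]
      a_removed <- c(a_removed, g$umis[drop_idx])
      a_target <- c(a_target, rep(g$umis[oi], res$map))
      a_post <- c(a_post, rep(res$posterior[res$map + 1], res$map))
      total_reads <- g$reads[oi] + sum(g$reads[drop_idx])
      qsum <- g$quals[[oi]] * g$reads[oi]
      for (i in drop_idx) qsum <- qsum + g$quals[[i]] * g$reads[i]
      g$quals[[oi]] <- qsum / total_reads
      g$reads[oi] <- total_reads
      alive[drop_idx] <- FALSE
    }
    g$umis <- g$umis[alive]
    g$reads <- g$reads[alive]
    g$quals <- g$quals[alive]
    if (!changed) break
  }
  if (iter == max_iterations && changed) {
    warn(sprintf("Bayesian UMI filter did not converge for %s/%s within %d iterations",
                 g$cb, g$gene, max_iterations))
  }
  audit <- if (length(a_removed) > 0) {
    tibble(cb = g$cb, gene = g$gene, removed_umi = a_removed,
           target_umi = a_target, posterior = a_post, method = "bayesian")
  }
  list(group = g, audit = audit)
}
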