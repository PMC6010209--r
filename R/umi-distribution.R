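# UMI frequency distribution and collision adjustment.
#
# When the UMI pool is small relative to the number of molecules of a gene,
# two molecules can draw the same UMI and the observed number of distinct
# UMIs k under-reports the true molecule count n. Under a uniform pool of
# size m the closed form n = -m*log(1 - k/m) applies; real droplet data have
# highly skewed UMI usage, so the adjustment is instead built stepwise from
# the empirical distribution: starting from n(1) = 1, each additional
# distinct UMI costs on average 1/p(new) draws, where p(new) is the chance
# that the next molecule's UMI has not been seen yet.

#' Estimate the empirical UMI frequency distribution
#'
#' Pools all molecules (distinct cb/gene/umi triples) across the dataset and
#' estimates p(u) as the relative frequency of each UMI sequence. Sequences
#' never observed carry no mass, but the nominal pool size 4^L is retained
#' for the uniform comparator.
#'
#' @param records A molecule record tibble.
#' @return An object of class `umi_distribution`: list with `probs` (named
#'   numeric, sums to 1), `pool_size` (number of observed sequences),
#'   `umi_length` and `n_possible` (4^L).
#' @export
estimate_umi_distribution <- function(records) {
  if (nrow(records) == 0) abort("cannot estimate a UMI distribution from an empty dataset")
  L <- umi_length(records)
  tab <- table(records$umi)
  probs <- as.numeric(tab) / sum(tab)
  names(probs) <- names(tab)
  umi_distribution(probs, umi_len = L)
}

#' Construct a UMI distribution object
#'
#' @param probs Named numeric vector of per-sequence probabilities.
#' @param umi_len UMI length L.
#' @return An `umi_distribution` object.
#' @export
umi_distribution <- function(probs, umi_len) {
  if (abs(sum(probs) - 1) > 1e-9) abort("UMI probabilities must sum to 1")
  if (any(probs <= 0)) abort("all retained UMI probabilities must be > 0")
  structure(
    list(
      probs = probs,
      pool_size = length(probs),
      umi_length = as.integer(umi_len),
      n_possible = 4^umi_len
    ),
    class = "umi_distribution"
  )
}

# Uniform distribution over the full 4^L pool (used by the uniform
# comparator and by tests).
uniform_umi_distribution <- function(umi_len) {
  m <- 4^umi_len
  seqs <- all_sequences(umi_len)
  umi_distribution(setNames(rep(1 / m, m), seqs), umi_len)
}

#' @export
print.umi_distribution <- function(x, ...) {
  cat(sprintf(
    "<umi_distribution> L = %d, %d observed sequences of %g possible, max p = %.4g\n",
    x$umi_length, x$pool_size, x$n_possible, max(x$probs)
  ))
  invisible(x)
}

#' Uniform-pool collision adjustment (closed form)
#'
#' Inverts the expected-distinct relation k = m(1 - exp(-n/m)) for a uniform
#' pool of m UMIs: n = -m*log(1 - k/m). When k/m is below `negligible` the
#' adjustment is numerically irrelevant and k is returned unchanged.
#'
#' @param k Observed distinct-UMI counts (vectorized).
#' @param m Pool size.
#' @param negligible Fraction of the pool below which no adjustment is made.
#' @return Estimated true molecule counts.
#' @export
collisions_uniform <- function(k, m, negligible = 0) {
  if (any(k < 0) || any(k >= m)) {
    abort("collisions_uniform() requires 0 <= k < m (saturated pool has no inverse)")
  }
  out <- -m * log(1 - k / m)
  small <- k / m < negligible
  out[small] <- k[small]
  out
}

#' Probability that the next molecule carries an unseen UMI
#'
#' For a current molecule count n, each pool sequence u_i is still unseen
#' with probability (1 - p(u_i))^n, so the chance that one more draw yields
#' a new distinct UMI is sum_i p(u_i) (1 - p(u_i))^n.
#'
#' @param dist An `umi_distribution`.
#' @param n Current molecule count estimate (non-negative real).
#' @return Probability in (0, 1].
#' @export
new_umi_probability <- function(dist, n) {
  if (n < 0) abort("n must be >= 0")
  p <- dist$probs
  sum(p * (1 - p)^n)
}

#' Build the stepwise collision-adjustment table
#'
#' Starting from n(1) = 1, each step adds the expected number of draws
#' needed to see one more distinct UMI: n(k+1) = n(k) + 1/p(new at n(k)).
#' The table is truncated at the pool size or when a single increment
#' exceeds `max_increment` (the pool is effectively saturated).
#'
#' @param dist An `umi_distribution`.
#' @param max_k Largest k to tabulate (default: pool size - 1).
#' @param max_increment Truncation cap on a single step.
#' @return An object of class `collision_table`: list with `n_of_k`
#'   (numeric vector indexed by k) and `pool_size`.
#' @export
build_collision_table <- function(dist, max_k = NULL, max_increment = 1e6) {
  m <- dist$pool_size
  max_k <- min(max_k %||% (m - 1L), m)
  max_k <- max(max_k, 1L)
  n_of_k <- numeric(max_k)
  n_of_k[1] <- 1
  if (max_k > 1) {
    for (k in 1:(max_k - 1)) {
      p_new <- new_umi_probability(dist, n_of_k[k])
      inc <- 1 / p_new
      if (!is.finite(inc) || inc > max_increment) {
        n_of_k <- n_of_k[1:k]
        break
      }
      n_of_k[k + 1] <- n_of_k[k] + inc
    }
  }
  structure(
    list(n_of_k = n_of_k, pool_size = m, umi_length = dist$umi_length),
    class = "collision_table"
  )
}

# Collision table under the uniform closed form, tabulated for k = 1..max_k.
uniform_collision_table <- function(m, max_k = m - 1, umi_len = NA_integer_) {
  ks <- seq_len(max_k)
  structure(
    list(n_of_k = -m * log(1 - ks / m), pool_size = m, umi_length = umi_len),
    class = "collision_table"
  )
}

#' @export
print.collision_table <- function(x, ...) {
  cat(sprintf(
    "<collision_table> pool %d, tabulated k = 1..%d, n(max) = %.1f\n",
    x$pool_size, length(x$n_of_k), max(x$n_of_k)
  ))
  invisible(x)
}

# Look up n(k) for integer k >= 0; errors past the tabulated range.
collision_lookup <- function(table, k) {
  out <- numeric(length(k))
  pos <- k > 0
  if (any(k[pos] > length(table$n_of_k))) {
    abort(sprintf(
      "count %d exceeds the collision table range (k <= %d); rebuild with a larger max_k",
      max(k), length(table$n_of_k)
    ))
  }
  out[pos] <- table$n_of_k[k[pos]]
  out
}

#' Apply collision adjustment to a count matrix
#'
#' Replaces each entry k (observed distinct UMIs) by the estimated true
#' molecule count n(k); zeros are untouched.
#'
#' @param matrix A genes-by-cells sparse count matrix.
#' @param table A `collision_table`.
#' @param negligible Skip the adjustment when max(k)/pool is below this.
#' @return The adjusted sparse matrix (real-valued).
#' @export
adjust_counts <- function(matrix, table, negligible = 0) {
  m <- methods::as(matrix, "CsparseMatrix")
  if (length(m@x) == 0) return(m)
  if (max(m@x) / table$pool_size < negligible) return(m)
  m@x <- collision_lookup(table, as.integer(round(m@x)))
  m
}

#' Serialize a collision table to TSV
#'
#' @param table A `collision_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_collision_table <- function(table, path) {
  readr::write_tsv(
    tibble(k = seq_along(table$n_of_k), n_of_k = table$n_of_k),
    path
  )
  invisible(path)
}
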