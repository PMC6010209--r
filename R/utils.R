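# Sequence utilities shared across modules. Barcodes and UMIs are plain
# character vectors over {A,C,G,T}; groups are small, so everything works on
# split character matrices and hashed lookups rather than Biostrings objects.

DNA_BASES <- c("A", "C", "G", "T")

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Character scalars of equal length.
#' @return Integer number of mismatching positions.
#' @keywords internal
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("hamming_distance() requires equal-length sequences")
  }
  sum(charToRaw(a) != charToRaw(b))
}

# All-pairs Hamming distances for a character vector of equal-length
# sequences; returns an integer matrix. Used by diagnostics and test oracles.
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(matrix(0L, n, n))
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  d <- matrix(0L, n, n)
  for (p in seq_len(ncol(chars))) {
    d <- d + outer(chars[, p], chars[, p], "!=")
  }
  d
}

#' Enumerate all sequences at Hamming distance 1
#'
#' @param seq Character scalar over ACGT.
#' @return Character vector of the 3*nchar(seq) Hamming-1 variants.
#' @keywords internal
hamming1_neighbors <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- character(3L * L)
  k <- 0L
  for (pos in seq_len(L)) {
    for (b in DNA_BASES) {
      if (b != chars[pos]) {
        k <- k + 1L
        v <- chars
        v[pos] <- b
        out[k] <- paste(v, collapse = "")
      }
    }
  }
  out
}

# Hamming-2 variants (exactly two substituted positions). Deterministic order.
hamming2_neighbors <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 2) return(character(0))
  out <- character(choose(L, 2) * 9L)
  k <- 0L
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      for (bi in DNA_BASES[DNA_BASES != chars[i]]) {
        for (bj in DNA_BASES[DNA_BASES != chars[j]]) {
          k <- k + 1L
          v <- chars
          v[i] <- bi
          v[j] <- bj
          out[k] <- paste(v, collapse = "")
        }
      }
    }
  }
  out
}

# Position of the single mismatch between two Hamming-1 sequences.
mismatch_position <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))[1]
}

# Random sequences of length L, seed-controlled by the caller.
random_sequences <- function(n, L) {
  vapply(
    seq_len(n),
    function(i) paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""),
    character(1)
  )
}

# All 4^L sequences in lexicographic order; guarded to keep memory sane.
all_sequences <- function(L) {
  if (L > 8) abort("all_sequences() supports L <= 8 (4^L sequences)")
  grid <- do.call(expand.grid, rep(list(DNA_BASES), L))
  # expand.grid varies the first factor fastest; flip for lexicographic order
  grid <- grid[, rev(seq_len(L)), drop = FALSE]
  sorted <- do.call(paste0, grid)
  sort(sorted)
}

assert_acgt <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-ACGT characters (first offender: row %d, '%s')",
      what, which(bad)[1], seqs[which(bad)[1]]
    ))
  }
  invisible(seqs)
}
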