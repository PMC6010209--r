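# Cellular barcode (CB) error correction.
#
# A sequencing error in a CB splits a fraction of a cell's molecules into a
# spurious child barcode. Because reads per molecule are generally > 1, the
# child retains many of the parent's exact gene-UMI pairs, so the molecular
# compositions of parent and child overlap far more than two independent
# cells would. The Poisson method tests, for every barcode, whether its
# composition overlap with each larger barcode within Hamming distance
# max_hamming could have arisen by chance: the observed intersection C is
# compared with its expectation EC under independent compositions (derived
# from the empirical UMI distribution with collision-adjusted gene sizes),
# and the tail P(Pois(EC) >= C) is Bonferroni-adjusted over the candidate
# set. Baselines: merge-by-proximity ("simple") and nearest-whitelist-entry
# ("known").

#' Build per-cell molecular compositions
#'
#' @param records A molecule record tibble (UMI-corrected).
#' @return A named list (by CB) of objects with `cb`, `genes` (named list of
#'   UMI character vectors) and `size` (total molecules).
#' @export
cell_compositions <- function(records) {
  records <- records[!records$intergenic, , drop = FALSE]
  by_cb <- split(seq_len(nrow(records)), records$cb)
  comps <- lapply(by_cb, function(i) {
    genes <- split(records$umi[i], records$gene[i])
    list(cb = records$cb[i[1]], genes = genes, size = length(i))
  })
  comps
}

#' Observed molecular-composition intersection of two cells
#'
#' Sum over shared genes of the UMI-set intersection sizes.
#'
#' @param a,b Compositions from [cell_compositions()].
#' @return Integer intersection size.
#' @export
observed_intersection <- function(a, b) {
  shared <- intersect(names(a$genes), names(b$genes))
  if (length(shared) == 0) return(0L)
  sum(vapply(shared, function(g) {
    length(intersect(a$genes[[g]], b$genes[[g]]))
  }, integer(1)))
}

# Memoized per-size vector of per-UMI occupancy probabilities
# 1 - (1 - p(u))^{S'}, where S' is the collision-adjusted gene size.
occupancy_cache <- function(dist, table) {
  env <- new.env(parent = emptyenv())
  function(size) {
    key <- as.character(size)
    v <- env[[key]]
    if (is.null(v)) {
      s_adj <- if (is.null(table)) size else collision_lookup(table, size)
      v <- 1 - (1 - dist$probs)^s_adj
      env[[key]] <- v
    }
    v
  }
}

#' Expected composition intersection of two independent cells
#'
#' For each shared gene, each pool UMI u is present in an independent
#' composition of adjusted size S' with probability 1 - (1 - p(u))^{S'};
#' the expected intersection is the sum over u of the product for the two
#' cells, summed over shared genes. Values are memoized on the (smaller,
#' larger) gene-size pair.
#'
#' @param a,b Compositions.
#' @param dist An `umi_distribution`.
#' @param table Optional `collision_table` for the S -> S' adjustment
#'   (`NULL` keeps S' = S).
#' @param occ Optional pre-built occupancy cache (internal reuse).
#' @return Non-negative expected intersection.
#' @export
expected_intersection <- function(a, b, dist, table = NULL, occ = NULL) {
  shared <- intersect(names(a$genes), names(b$genes))
  if (length(shared) == 0) return(0)
  if (is.null(occ)) occ <- occupancy_cache(dist, table)
  sum(vapply(shared, function(g) {
    sum(occ(length(a$genes[[g]])) * occ(length(b$genes[[g]])))
  }, numeric(1)))
}

#' Poisson tail test for a composition intersection
#'
#' P(X >= C) for X ~ Poisson(EC); the p value of the null hypothesis that
#' the observed overlap arose between independent cells.
#'
#' @param C Observed intersection (integer).
#' @param EC Expected intersection under independence.
#' @return p value in (0, 1].
#' @export
poisson_merge_test <- function(C, EC) {
  if (EC < 0) abort("EC must be >= 0")
  if (C <= 0) return(1)
  ppois(C - 1, lambda = EC, lower.tail = FALSE)
}

# Candidate CBs within Hamming distance max_hamming of cb, found by
# neighbourhood enumeration against a lookup of existing barcodes.
cb_candidates <- function(cb, cb_index, max_hamming = 2L) {
  variants <- hamming1_neighbors(cb)
  if (max_hamming >= 2L) variants <- c(variants, hamming2_neighbors(cb))
  hits <- cb_index[variants]
  sort(unique(hits[!is.na(hits)]))
}

empty_merge_plan <- function(method) {
  structure(
    tibble(
      source = character(), target = character(),
      C = integer(), EC = numeric(),
      p_raw = numeric(), p_adj = numeric(), method = character()
    ),
    class = c("merge_plan", "tbl_df", "tbl", "data.frame"),
    method = method
  )
}

#' Merge cellular barcodes via the Poisson composition test
#'
#' Each barcode is compared against all barcodes with at least as many
#' molecules within Hamming distance `max_hamming`; p values are Bonferroni
#' adjusted per source over its candidate count and the source merges into
#' the candidate with the smallest adjusted p value when it is below
#' `alpha`. Sources are processed smallest-first in one pass and a barcode
#' that has received a merge is never itself merged away (the plan is a
#' one-level forest).
#'
#' @param records A molecule record tibble (UMI-corrected).
#' @param dist An `umi_distribution` (estimated from `records` if missing).
#' @param table Optional `collision_table` for adjusted gene sizes.
#' @param max_hamming Maximum CB Hamming distance (CBs of unequal length are
#'   never candidates).
#' @param alpha Significance level on the Bonferroni-adjusted p value.
#' @return A `merge_plan` tibble: source, target, C, EC, p_raw, p_adj,
#'   method.
#' @export
merge_poisson <- function(records, dist = NULL, table = NULL,
                          max_hamming = 2L, alpha = 0.01) {
  comps <- cell_compositions(records)
  if (length(comps) == 0) return(empty_merge_plan("poisson"))
  if (is.null(dist)) dist <- estimate_umi_distribution(records)
  occ <- occupancy_cache(dist, table)
  cbs <- names(comps)
  sizes <- vapply(comps, `[[`, numeric(1), "size")
  cb_index <- setNames(seq_along(cbs), cbs)
  ord <- order(sizes, cbs)  # smallest first
  merged_away <- rep(FALSE, length(cbs))
  received <- rep(FALSE, length(cbs))
  plan <- NULL
  for (i in ord) {
    if (received[i]) next
    cand <- cb_candidates(cbs[i], cb_index, max_hamming)
    cand <- cand[!merged_away[cand] & cand != i]
    cand <- cand[sizes[cand] > sizes[i] |
                   (sizes[cand] == sizes[i] & cbs[cand] > cbs[i])]
    if (length(cand) == 0) next
    C <- vapply(cand, function(j) observed_intersection(comps[[i]], comps[[j]]), integer(1))
    EC <- vapply(cand, function(j) expected_intersection(comps[[i]], comps[[j]], dist, table, occ = occ), numeric(1))
    p_raw <- mapply(poisson_merge_test, C, EC)
    p_adj <- pmin(1, p_raw * length(cand))
    best <- order(p_adj, -sizes[cand], cbs[cand])[1]
    if (p_adj[best] < alpha) {
      j <- cand[best]
      merged_away[i] <- TRUE
      received[j] <- TRUE
      plan <- bind_rows(plan, tibble(
        source = cbs[i], target = cbs[j],
        C = C[best], EC = EC[best],
        p_raw = p_raw[best], p_adj = p_adj[best], method = "poisson"
      ))
    }
  }
  if (is.null(plan)) return(empty_merge_plan("poisson"))
  structure(plan, class = c("merge_plan", class(plan)), method = "poisson")
}

#' Merge cellular barcodes by sequence proximity alone
#'
#' Every barcode with a strictly larger barcode within `max_hamming` merges
#' into the largest such neighbour (ties by lexicographic order).
#'
#' @inheritParams merge_poisson
#' @return A `merge_plan` tibble.
#' @export
merge_simple <- function(records, max_hamming = 2L) {
  comps <- cell_compositions(records)
  if (length(comps) == 0) return(empty_merge_plan("simple"))
  cbs <- names(comps)
  sizes <- vapply(comps, `[[`, numeric(1), "size")
  cb_index <- setNames(seq_along(cbs), cbs)
  plan <- NULL
  for (i in seq_along(cbs)) {
    cand <- cb_candidates(cbs[i], cb_index, max_hamming)
    cand <- cand[sizes[cand] > sizes[i]]
    if (length(cand) == 0) next
    j <- cand[order(-sizes[cand], cbs[cand])[1]]
    plan <- bind_rows(plan, tibble(
      source = cbs[i], target = cbs[j],
      C = NA_integer_, EC = NA_real_,
      p_raw = NA_real_, p_adj = NA_real_, method = "simple"
    ))
  }
  if (is.null(plan)) return(empty_merge_plan("simple"))
  # forest constraint: a target never appears as a source
  plan <- plan[!(plan$source %in% plan$target), , drop = FALSE]
  structure(plan, class = c("merge_plan", class(plan)), method = "simple")
}

#' Reassign barcodes to a known whitelist
#'
#' Non-whitelist barcodes move to the nearest whitelist barcode (Hamming)
#' holding at least as many molecules; equidistant ties are resolved by the
#' Poisson composition test when `dist` is supplied, otherwise by larger
#' size then lexicographic order. Barcodes farther than `max_hamming` from
#' every valid barcode are placed on a reject list (attribute
#' `"rejected"`).
#'
#' @inheritParams merge_poisson
#' @param whitelist Character vector of valid barcodes.
#' @return A `merge_plan` tibble with attribute `"rejected"`.
#' @export
merge_known_barcodes <- function(records, whitelist, dist = NULL, table = NULL,
                                 max_hamming = 2L) {
  if (length(whitelist) == 0) abort("whitelist must be non-empty")
  comps <- cell_compositions(records)
  cbs <- names(comps)
  sizes <- vapply(comps, `[[`, numeric(1), "size")
  wl_sizes <- setNames(rep(0, length(whitelist)), whitelist)
  present <- intersect(whitelist, cbs)
  wl_sizes[present] <- sizes[present]
  use_test <- !is.null(dist)
  occ <- if (use_test) occupancy_cache(dist, table)
  plan <- NULL
  rejected <- character()
  for (i in seq_along(cbs)) {
    cb <- cbs[i]
    if (cb %in% whitelist) next
    if (nchar(cb) != nchar(whitelist[1])) {
      rejected <- c(rejected, cb)
      next
    }
    d <- vapply(whitelist, function(w) hamming_distance(cb, w), numeric(1))
    ok <- d <= max_hamming & wl_sizes >= sizes[i]
    if (!any(ok)) {
      rejected <- c(rejected, cb)
      next
    }
    dmin <- min(d[ok])
    near <- whitelist[ok & d == dmin]
    if (length(near) > 1) {
      if (use_test) {
        p <- vapply(near, function(w) {
          if (!w %in% cbs) return(1)
          C <- observed_intersection(comps[[cb]], comps[[w]])
          EC <- expected_intersection(comps[[cb]], comps[[w]], dist, table, occ = occ)
          poisson_merge_test(C, EC)
        }, numeric(1))
        near <- near[order(p, -wl_sizes[near], near)]
      } else {
        near <- near[order(-wl_sizes[near], near)]
      }
    }
    plan <- bind_rows(plan, tibble(
      source = cb, target = near[1],
      C = NA_integer_, EC = NA_real_,
      p_raw = NA_real_, p_adj = NA_real_, method = "known"
    ))
  }
  plan <- if (is.null(plan)) empty_merge_plan("known") else
    structure(plan, class = c("merge_plan", class(plan)), method = "known")
  attr(plan, "rejected") <- rejected
  plan
}

#' Apply a merge plan to a record table
#'
#' Relabels source barcodes to their targets and re-aggregates duplicate
#' (cb, umi, gene) keys (reads summed, qualities read-weight averaged), so
#' total reads are conserved and molecule sets take union semantics.
#'
#' @param records A molecule record tibble.
#' @param plan A `merge_plan`.
#' @return The merged record tibble.
#' @export
apply_merge <- function(records, plan) {
  if (nrow(plan) == 0) return(records)
  if (any(plan$target %in% plan$source)) {
    abort("merge plan contains chains (a target also appears as a source)")
  }
  if (anyDuplicated(plan$source)) abort("merge plan maps a source twice")
  map <- setNames(plan$target, plan$source)
  hit <- records$cb %in% names(map)
  records$cb[hit] <- unname(map[records$cb[hit]])
  aggregate_records(records)
}

#' Audit merges on two-species data
#'
#' On a dataset whose genes carry species labels, counts how often merges
#' join barcodes assigned to different species — a direct readout of false
#' merges, since a barcode's molecules should come from one organism.
#' Cells with fewer than `min_genes` expressed genes are excluded; each
#' remaining cell is assigned the species with more molecules; the
#' `n_real` largest cells are deemed real and only merges into real cells
#' are counted.
#'
#' @param plan A `merge_plan`.
#' @param records The record tibble the plan was computed on.
#' @param species_of_gene Named character vector gene -> species.
#' @param min_genes Minimal expressed genes per audited cell.
#' @param n_real Number of largest cells considered real.
#' @param reference_plan Optional second plan; the fraction of sources with
#'   the same target in both plans is reported as `agreement`.
#' @return A tibble with one row: n_merges, n_cross_species,
#'   cross_species_fraction, agreement.
#' @export
cross_species_merge_audit <- function(plan, records, species_of_gene,
                                      min_genes = 10, n_real = 100,
                                      reference_plan = NULL) {
  stats <- records %>%
    filter(!.data$intergenic) %>%
    mutate(species = unname(species_of_gene[.data$gene])) %>%
    group_by(.data$cb) %>%
    summarise(
      n_genes = dplyr::n_distinct(.data$gene),
      size = n(),
      species = names(which.max(table(.data$species))),
      .groups = "drop"
    ) %>%
    filter(.data$n_genes >= min_genes)
  real <- stats %>% arrange(desc(.data$size), .data$cb) %>% head(n_real) %>% pull(.data$cb)
  sp <- setNames(stats$species, stats$cb)
  audited <- plan %>%
    filter(.data$target %in% real,
           .data$source %in% stats$cb)
  n_merges <- nrow(audited)
  n_cross <- sum(sp[audited$source] != sp[audited$target])
  agreement <- NA_real_
  if (!is.null(reference_plan) && nrow(plan) > 0) {
    common <- intersect(plan$source, reference_plan$source)
    if (length(common) > 0) {
      t1 <- setNames(plan$target, plan$source)[common]
      t2 <- setNames(reference_plan$target, reference_plan$source)[common]
      agreement <- mean(t1 == t2)
    }
  }
  tibble(
    n_merges = n_merges,
    n_cross_species = n_cross,
    cross_species_fraction = if (n_merges > 0) n_cross / n_merges else 0,
    agreement = agreement
  )
}
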