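test_that("observed intersection counts shared gene-UMI pairs", {
  rec <- dplyr::bind_rows(
    make_records("c1", c("AA", "AT", "GG"), c("g1", "g1", "g2"), 1),
    make_records("c2", c("AA", "AT", "CC"), c("g1", "g3", "g2"), 1)
  )
  comps <- cell_compositions(rec)
  expect_equal(observed_intersection(comps[["c1"]], comps[["c2"]]), 1L)  # g1/AA
  expect_equal(observed_intersection(comps[["c1"]], comps[["c1"]]), 3L)  # identity
  rec2 <- dplyr::bind_rows(
    make_records("a", c("AA", "AT"), "g1", 1),
    make_records("b", c("AA", "AT"), "g9", 1)
  )
  comps2 <- cell_compositions(rec2)
  expect_equal(observed_intersection(comps2[["a"]], comps2[["b"]]), 0L)  # no shared gene
  # brute-force oracle on random compositions
  set.seed(3)
  for (rep in 1:20) {
    recr <- make_records(
      cb = sample(c("x", "y"), 40, replace = TRUE),
      umi = sample(dropcount:::all_sequences(2), 40, replace = TRUE),
      gene = sample(c("g1", "g2", "g3"), 40, replace = TRUE),
      reads = 1
    )
    recr <- aggregate_records(recr)
    cm <- cell_compositions(recr)
    if (length(cm) < 2) next
    brute <- 0
    for (g in intersect(names(cm[[1]]$genes), names(cm[[2]]$genes))) {
      brute <- brute + length(intersect(cm[[1]]$genes[[g]], cm[[2]]$genes[[g]]))
    }
    expect_equal(observed_intersection(cm[[1]], cm[[2]]), brute)
  }
})

test_that("expected intersection matches closed form and Monte-Carlo draws", {
  unif <- dropcount:::uniform_umi_distribution(2)  # m = 16
  rec <- dplyr::bind_rows(
    make_records("c1", "AA", "g1", 1),
    make_records("c2", "AT", "g1", 1)
  )
  comps <- cell_compositions(rec)
  expect_equal(expected_intersection(comps[["c1"]], comps[["c2"]], unif), 1 / 16)
  # symmetry
  expect_equal(expected_intersection(comps[["c1"]], comps[["c2"]], unif),
               expected_intersection(comps[["c2"]], comps[["c1"]], unif))
  # disjoint gene sets
  rec2 <- dplyr::bind_rows(make_records("c1", "AA", "g1", 1),
                           make_records("c2", "AA", "g2", 1))
  comps2 <- cell_compositions(rec2)
  expect_equal(expected_intersection(comps2[["c1"]], comps2[["c2"]], unif), 0)

  # Monte-Carlo oracle: skewed 16-UMI pool, gene sizes 5 and 8
  set.seed(19)
  w <- rgamma(16, 0.8)
  probs <- setNames(w / sum(w), dropcount:::all_sequences(2))
  dist <- umi_distribution(probs, 2)
  rec3 <- dplyr::bind_rows(
    make_records("c1", sample(names(probs), 5), "g1", 1),
    make_records("c2", sample(names(probs), 8), "g1", 1)
  )
  comps3 <- cell_compositions(rec3)
  ec <- expected_intersection(comps3[["c1"]], comps3[["c2"]], dist)
  n_sim <- 2e4
  draw_set <- function(n) unique(sample(names(probs), n, replace = TRUE, prob = probs))
  # sizes 5 and 8 are *adjusted* sizes here (no collision table): simulate
  # compositions by drawing that many molecules
  sims <- vapply(seq_len(n_sim), function(i) {
    length(intersect(draw_set(5), draw_set(8)))
  }, numeric(1))
  se <- stats::sd(sims) / sqrt(n_sim)
  expect_lt(abs(mean(sims) - ec), 3 * se + 0.02)
})

test_that("Poisson tail equals the truncated series", {
  expect_equal(poisson_merge_test(0, 2.5), 1)
  expect_equal(poisson_merge_test(3, 0.5),
               1 - exp(-0.5) * (1 + 0.5 + 0.125), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:100) {
    C <- sample(1:12, 1)
    EC <- runif(1, 0, 6)
    # direct series: sum the upper-tail mass term by term
    series <- sum(exp(-EC) * EC^(C:(C + 60)) / factorial(C:(C + 60)))
    expect_equal(poisson_merge_test(C, EC), series, tolerance = 1e-9)
  }
})

test_that("poisson merge joins split barcodes but not distant or disjoint ones", {
  set.seed(23)
  pool <- dropcount:::all_sequences(3)
  parent_rec <- make_records("AAAAAA", sample(pool, 40), paste0("g", rep(1:4, 10)), 2)
  child_rec <- parent_rec[1:8, ]          # 20% of molecules, same gene-UMI pairs
  child_rec$cb <- "AAAAAT"                 # Hamming 1
  far_rec <- parent_rec[9:16, ]
  far_rec$cb <- "TTTAAA"                   # Hamming 3: never a candidate
  indep <- make_records("AAAATA", sample(setdiff(pool, parent_rec$umi), 10),
                        paste0("g", rep(5:6, 5)), 2)  # disjoint genes
  rec <- dplyr::bind_rows(parent_rec, child_rec, far_rec, indep)
  plan <- merge_poisson(rec, alpha = 0.01)
  expect_true(all(c("AAAAAT") %in% plan$source))
  expect_equal(plan$target[plan$source == "AAAAAT"], "AAAAAA")
  expect_false("TTTAAA" %in% plan$source)
  expect_false("AAAATA" %in% plan$source)
})

test_that("simple merge picks the largest neighbour and keeps isolated barcodes", {
  rec <- dplyr::bind_rows(
    make_records("AAAA", dropcount:::all_sequences(2)[1:10], "g1", 1),
    make_records("AAAT", dropcount:::all_sequences(2)[1:6], "g1", 1),
    make_records("AATT", dropcount:::all_sequences(2)[1:3], "g1", 1),
    make_records("GGGG", dropcount:::all_sequences(2)[1:4], "g1", 1)
  )
  plan <- merge_simple(rec, max_hamming = 2)
  expect_equal(plan$target[plan$source == "AATT"], "AAAA")  # largest within 2
  expect_false("GGGG" %in% plan$source)                     # isolated
  expect_false(any(plan$target %in% plan$source))           # forest
})

test_that("known-barcode merge reassigns to the nearest valid barcode", {
  wl <- c("AAAA", "CCCC", "GGGG")
  rec <- dplyr::bind_rows(
    make_records("AAAA", dropcount:::all_sequences(2)[1:10], "g1", 1),
    make_records("AAAT", dropcount:::all_sequences(2)[1:3], "g1", 1),  # H1 from AAAA
    make_records("CCCC", dropcount:::all_sequences(2)[1:8], "g1", 1),
    make_records("TTTT", dropcount:::all_sequences(2)[1:2], "g1", 1)   # H>2 from all
  )
  plan <- merge_known_barcodes(rec, wl, max_hamming = 2)
  expect_false("AAAA" %in% plan$source)  # already valid
  expect_equal(plan$target[plan$source == "AAAT"], "AAAA")
  expect_equal(attr(plan, "rejected"), "TTTT")
})

test_that("applying a merge plan conserves reads and unions molecule sets", {
  rec <- dplyr::bind_rows(
    make_records("AAAA", c("AA", "AT"), "g1", c(3, 2)),
    make_records("AAAT", c("AA", "GG"), "g1", c(1, 4))
  )
  plan0 <- dropcount:::empty_merge_plan("poisson")
  expect_identical(apply_merge(rec, plan0), rec)
  plan <- tibble::tibble(source = "AAAT", target = "AAAA", C = 1L, EC = 0.1,
                         p_raw = 0.01, p_adj = 0.01, method = "poisson")
  merged <- apply_merge(rec, plan)
  expect_equal(sum(merged$reads), sum(rec$reads))
  expect_setequal(merged$umi[merged$cb == "AAAA"], c("AA", "AT", "GG"))
  expect_equal(merged$reads[merged$cb == "AAAA" & merged$umi == "AA"], 4)
  chain <- tibble::tibble(source = c("a", "b"), target = c("b", "c"),
                          C = NA_integer_, EC = NA_real_,
                          p_raw = NA_real_, p_adj = NA_real_, method = "x")
  expect_error(apply_merge(rec, chain), "chains")
})

test_that("cross-species audit flags false merges and scores plan agreement", {
  sim <- cached("species_sim", simulate_dataset(simulation_config(
    n_cells = 60, n_background = 150, n_genes = 30, seed = 13,
    cell_size_meanlog = log(500), two_species = TRUE, cb_error_rate = 0.3
  )))
  rec <- cached("species_rec", correct_umi_errors(sim$records, method = "cluster"))
  empty_audit <- cross_species_merge_audit(
    dropcount:::empty_merge_plan("poisson"), rec, sim$truth$species_of_gene,
    min_genes = 5, n_real = 60
  )
  expect_equal(empty_audit$n_merges, 0)
  expect_equal(empty_audit$cross_species_fraction, 0)

  plan_p <- cached("species_plan_p", merge_poisson(rec, alpha = 0.01))
  plan_s <- merge_simple(rec)
  aud_p <- cross_species_merge_audit(plan_p, rec, sim$truth$species_of_gene,
                                     min_genes = 5, n_real = 60)
  aud_s <- cross_species_merge_audit(plan_s, rec, sim$truth$species_of_gene,
                                     min_genes = 5, n_real = 60)
  # composition-tested merges stay within species; proximity merges cross
  expect_lt(aud_p$cross_species_fraction, 0.05)
  expect_gt(aud_s$cross_species_fraction, aud_p$cross_species_fraction)
  # simple merges strictly more pairs than poisson
  expect_gt(nrow(plan_s), nrow(plan_p))

  # known-barcode plan built from the true barcode list agrees with poisson
  wl <- sim$truth$cells$cb
  plan_k <- merge_known_barcodes(rec, wl, dist = estimate_umi_distribution(rec))
  aud_agree <- cross_species_merge_audit(plan_p, rec, sim$truth$species_of_gene,
                                         min_genes = 5, n_real = 60,
                                         reference_plan = plan_k)
  expect_gte(aud_agree$agreement, 0.99)
})
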