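test_that("observed edit-distance profile pools pairwise distances per group", {
  rec <- make_records("c1", c("AAAA", "AAAT"), "g1", 1)
  obs <- observed_edit_distribution(rec)
  expect_equal(obs$probability, c(0, 1, 0, 0, 0))  # point mass at distance 1
  expect_equal(sum(obs$probability), 1)
  expect_error(observed_edit_distribution(make_records("c1", "AAAA", "g1", 1)),
               "two or more")
  # brute-force pooling oracle across several groups
  set.seed(15)
  recs <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_records(paste0("c", i %% 2), unique(dropcount:::random_sequences(5, 3)),
                 paste0("g", i), 1)
  }))
  obs2 <- observed_edit_distribution(recs)
  pooled <- c()
  for (key in unique(paste(recs$cb, recs$gene))) {
    part <- recs[paste(recs$cb, recs$gene) == key, ]
    if (nrow(part) < 2) next
    d <- dropcount:::hamming_matrix(part$umi)
    pooled <- c(pooled, d[upper.tri(d)])
  }
  expect_equal(obs2$probability, tabulate(pooled + 1, 4) / length(pooled))
})

test_that("theoretical edit-distance profile matches the binomial for a uniform pool", {
  unif <- dropcount:::uniform_umi_distribution(3)
  theo <- theoretical_edit_distribution(unif, n_pairs = 5e4, seed = 4)
  ref <- dbinom(0:3, 3, 3 / 4)
  se <- sqrt(ref * (1 - ref) / 5e4)
  expect_true(all(abs(theo$probability - ref) <= 3 * se + 1e-3))
  # degenerate pool: all pairs identical
  degen <- umi_distribution(setNames(1, "AAA"), 3)
  expect_equal(theoretical_edit_distribution(degen, 1e4, seed = 1)$probability[1], 1)
  # two seeds agree within Monte-Carlo error
  t1 <- theoretical_edit_distribution(unif, 5e4, seed = 1)
  t2 <- theoretical_edit_distribution(unif, 5e4, seed = 2)
  expect_true(all(abs(t1$probability - t2$probability) < 0.02))
  expect_error(theoretical_edit_distribution(unif, 100), "1e4")
})

test_that("relative difference is zero on identical profiles and hand-checkable", {
  p <- tibble::tibble(distance = 0:2, probability = c(0.2, 0.5, 0.3))
  d <- edit_distance_relative_difference(p, p)
  expect_equal(d$relative_difference, rep(0, 3))
  q <- tibble::tibble(distance = 0:2, probability = c(0, 1, 0))
  d2 <- edit_distance_relative_difference(q, p)
  expect_equal(d2$relative_difference, c(1, 0.5 / 0.5, 1))
  zero <- tibble::tibble(distance = 0:2, probability = c(0, 0.5, 0.5))
  d3 <- edit_distance_relative_difference(p, zero)
  expect_true(is.na(d3$relative_difference[1]))
})

test_that("UMI trimming merges collided records with weighted qualities", {
  rec <- dplyr::bind_rows(
    make_records("c1", "AAAT", "g1", 3, quals = list(rep(30, 4))),
    make_records("c1", "AAAG", "g1", 1, quals = list(rep(10, 4)))
  )
  tr <- trim_umis(rec, 3, side = "back")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$umi, "AAA")
  expect_equal(tr$reads, 4)
  expect_equal(tr$quals[[1]], rep(25, 3))  # (3*30 + 1*10) / 4
  expect_error(trim_umis(rec, 4), "new_length")
  # front trimming keeps the suffix
  tr_f <- trim_umis(rec, 2, side = "front")
  expect_setequal(tr_f$umi, c("AT", "AG"))
  # no collisions: molecule count unchanged, reads conserved
  rec2 <- make_records("c1", c("AAAA", "CCCC", "GGGG"), "g1", c(2, 3, 4))
  tr2 <- trim_umis(rec2, 2)
  expect_equal(nrow(tr2), 3)
  expect_equal(sum(tr2$reads), sum(rec2$reads))
})

test_that("rank curve mass integrates to the total molecule count", {
  set.seed(2)
  sizes <- round(rlnorm(300, log(50), 1)) + 1
  rc <- rank_curves(sizes)
  expect_equal(sum(rc$mass_curve$mass), sum(sizes))
  expect_equal(rc$rank_curve$size, sort(sizes, decreasing = TRUE))
})

test_that("adjacency excess is near 1 without errors and large with them", {
  no_err <- cached("sim_no_err", simulate_dataset(simulation_config(
    n_cells = 15, n_background = 30, n_genes = 15, seed = 41,
    cell_size_meanlog = log(400), umi_error_rate = 0, cb_error_rate = 0
  )))
  ex0 <- adjacency_excess(no_err$records, n_sim = 100, seed = 3)
  expect_gt(ex0$ratio, 0.7)
  expect_lt(ex0$ratio, 1.4)
  with_err <- cached("sim_with_err", simulate_dataset(simulation_config(
    n_cells = 15, n_background = 30, n_genes = 15, seed = 41,
    cell_size_meanlog = log(400), umi_error_rate = 0.02, cb_error_rate = 0
  )))
  ex1 <- adjacency_excess(with_err$records, n_sim = 100, seed = 3)
  expect_gt(ex1$ratio, 1.5)
  # no multi-UMI groups: undefined
  single <- make_records("c1", c("AAAA", "CCCC"), c("g1", "g2"), 1)
  expect_true(is.na(adjacency_excess(single)$ratio))
})

test_that("run report is valid JSON, reproducible and self-consistent", {
  rec <- make_records("c1", c("AAAA", "AAAT", "CCCC"), c("g1", "g1", "g2"), c(2, 1, 4))
  cfg <- run_config(seed = 11L)
  rep1 <- run_report(rec, cfg)
  expect_equal(rep1$n_molecules, 3)
  expect_equal(rep1$n_reads, 7)
  expect_equal(rep1$seed, 11L)
  dir <- withr::local_tempdir()
  write_run_report(rep1, file.path(dir, "a_"))
  write_run_report(rep1, file.path(dir, "b_"))
  expect_identical(readLines(file.path(dir, "a_report.json")),
                   readLines(file.path(dir, "b_report.json")))
  parsed <- jsonlite::read_json(file.path(dir, "a_report.json"))
  expect_equal(parsed$n_cells, 1)
  # empty dataset still yields a valid report
  rep0 <- run_report(dropcount:::empty_records(), cfg)
  expect_equal(rep0$n_molecules, 0)
  write_run_report(rep0, file.path(dir, "c_"))
  expect_silent(jsonlite::read_json(file.path(dir, "c_report.json")))
})

test_that("correction brings the edit-distance profile toward the theoretical one", {
  # moderately saturated data: errors inflate adjacent pairs, the Bayesian
  # filter removes them without flattening true adjacency
  sim <- cached("moderate_sim", simulate_dataset(simulation_config(
    n_cells = 15, n_background = 50, n_genes = 20, seed = 8,
    cell_size_meanlog = log(600), umi_error_rate = 0.01
  )))
  dist <- estimate_umi_distribution(sim$records)
  theo <- theoretical_edit_distribution(dist, n_pairs = 1e5, seed = 99)
  sumrel <- function(rec) {
    obs <- observed_edit_distribution(rec, seed = 99)
    d <- edit_distance_relative_difference(obs, theo)
    sum(d$relative_difference[d$distance > 0], na.rm = TRUE)
  }
  raw <- sumrel(sim$records)
  bayes <- sumrel(correct_umi_errors(sim$records, method = "bayesian"))
  clust <- sumrel(correct_umi_errors(sim$records, method = "cluster"))
  expect_lt(bayes, raw)
  expect_lt(bayes, clust)
})

test_that("trimming to full length is a no-op guard in the benchmark", {
  sim <- cached("moderate_sim", simulate_dataset(simulation_config(
    n_cells = 15, n_background = 50, n_genes = 20, seed = 8,
    cell_size_meanlog = log(600), umi_error_rate = 0.01
  )))
  small <- sim$records[sim$records$cb %in% unique(sim$records$cb)[1:20], ]
  bench <- trimming_benchmark(small, lengths = 5, methods = "cluster",
                              adjustments = "none", benchmark_method = "cluster")
  expect_true(all(c("percent_error", "expression_bin") %in% names(bench)))
  # the benchmark's own reference has zero error against itself
  ref <- correct_umi_errors(small, method = "cluster")
  counts <- dplyr::count(dplyr::filter(ref, !intergenic), cb, gene)
  expect_true(all(counts$n >= 1))
})
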