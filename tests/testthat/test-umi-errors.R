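test_that("neighbourhood view splits adjacent UMIs by read count", {
  g1 <- make_group("AAAA", 10)
  v <- adjacent_umis("AAAA", g1)
  expect_equal(nrow(v$omega), 0)
  expect_equal(c(v$n_s, v$n_l), c(0, 0))

  g2 <- make_group(c("AAAA", "AAAT", "TAAA"), c(10, 3, 12))
  v2 <- adjacent_umis("AAAA", g2)
  expect_equal(v2$n_s, 1)
  expect_equal(v2$n_l, 1)
  expect_equal(v2$omega$umi[v2$omega$side == "small"], "AAAT")
  expect_error(adjacent_umis("GGGG", g2), "not present")
})

test_that("neighbourhood membership agrees with brute-force pair distances", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    umis <- unique(dropcount:::random_sequences(n, 3))
    g <- make_group(umis, sample(1:20, length(umis), replace = TRUE))
    u <- sample(umis, 1)
    v <- adjacent_umis(u, g)
    brute <- umis[umis != u &
                    vapply(umis, function(x) sum(charToRaw(x) != charToRaw(u)), numeric(1)) == 1]
    expect_setequal(v$omega$umi, brute)
  }
})

test_that("cluster filter drops dominated UMIs with a deterministic tie-break", {
  expect_equal(cluster_filter(make_group(c("AAAA", "AAAT"), c(10, 1))), "AAAA")
  expect_setequal(cluster_filter(make_group(c("AAAA", "TTTT"), c(5, 5))),
                  c("AAAA", "TTTT"))  # distance 4: not adjacent
  tie <- make_group(c("AAAA", "AAAT"), c(5, 5))
  expect_equal(cluster_filter(tie), "AAAA")          # lexicographic winner
  expect_setequal(cluster_filter(tie, neq = TRUE), c("AAAA", "AAAT"))
})

test_that("directional filter uses the strict two-fold rule over the network", {
  expect_equal(directional_filter(make_group(c("AAAA", "AAAT"), c(10, 4))), "AAAA")
  expect_setequal(directional_filter(make_group(c("AAAA", "AAAT"), c(10, 5))),
                  c("AAAA", "AAAT"))  # 10 = 2*5: not strictly more
  # chain A-B-C absorbs transitively to the root
  chain <- make_group(c("AAAA", "AAAT", "AATT"), c(100, 40, 15))
  expect_equal(directional_filter(chain), "AAAA")
  # oracle: iterate absorption along the directed network until fixpoint
  set.seed(13)
  for (rep in 1:30) {
    umis <- unique(dropcount:::random_sequences(sample(3:8, 1), 2))
    reads <- sample(1:60, length(umis), replace = TRUE)
    g <- make_group(umis, reads)
    hm <- dropcount:::hamming_matrix(umis)
    dropped <- rep(FALSE, length(umis))
    repeat {
      new_drop <- vapply(seq_along(umis), function(i) {
        nb <- which(hm[i, ] == 1)
        any(reads[nb] > 2 * reads[i])
      }, logical(1))
      if (identical(new_drop, dropped)) break
      dropped <- new_drop
    }
    expect_setequal(directional_filter(g), umis[!dropped])
  }
})

test_that("quality model training recovers the per-read error rate", {
  # two training genes with adjacent pairs (r=1,R=9) and (r=2,R=8)
  rec <- dplyr::bind_rows(
    make_records("c1", c("AAAA", "AAAT"), "g1", c(9, 1),
                 quals = list(rep(35, 4), rep(35, 4))),
    make_records("c1", c("CCCC", "CCCG"), "g2", c(8, 2),
                 quals = list(rep(35, 4), rep(10, 4)))
  )
  qm <- train_quality_model(rec, k_q = 15)
  expect_equal(qm$p_e, 3 / 20)
  expect_equal(qm$n_training_pairs, 2)
  expect_error(
    train_quality_model(make_records("c1", c("AAAA", "TTTT"), "g1", 1)),
    "no training pairs"
  )
})

test_that("degenerate quantization collapses quality information", {
  rec <- dplyr::bind_rows(
    make_records("c1", c("AAAA", "AAAT"), "g1", c(9, 1)),
    make_records("c1", c("CCCC", "CCCG"), "g2", c(8, 2))
  )
  qm <- train_quality_model(rec, k_q = 1)
  expect_equal(length(qm$support), 1)
  expect_equal(qm$p_q, 1)
  expect_equal(qm$p_q_err, 1)
})

test_that("error-conditional quality concentrates at the injected low level", {
  sim <- saturated_sim()
  qm <- train_quality_model(sim$records)
  low <- qm$support <= 20
  expect_gt(sum(qm$p_q_err[low]), 0.6)          # errors mostly low quality
  expect_gt(sum(qm$p_q_err[low]), sum(qm$p_q[low]))  # and enriched vs background
})

test_that("adjacency prior columns are proper distributions with the stated anchors", {
  pr <- build_adjacency_prior(S_max = 8, L = 2, dp_step = 0.01)  # K = 6
  for (p in c(0.05, 0.3, 0.8)) {
    tab <- prior_table(pr, p)
    pq <- ceiling(p / 0.01) * 0.01  # cache grid value actually used
    expect_equal(colSums(tab), rep(1, 9), tolerance = 1e-9)
    expect_equal(tab[1:2, 2], c(1 - pq, pq))                 # one pick
    expect_equal(tab[1, ], (1 - pq)^(0:8), tolerance = 1e-12)  # never-adjacent run
    for (s in 0:5) expect_true(all(tab[(s + 2):7, s + 1] == 0))  # t_{k,s} = 0 for k > s
  }
  # stochastic ordering: larger adjacency mass shifts N' upward
  t1 <- prior_table(pr, 0.2)
  t2 <- prior_table(pr, 0.6)
  tail1 <- rev(cumsum(rev(t1[, 9])))
  tail2 <- rev(cumsum(rev(t2[, 9])))
  expect_true(all(tail2 >= tail1 - 1e-12))
})

test_that("adjacency DP matches exhaustive enumeration of the picking process", {
  # oracle: enumerate all 2^s pick outcomes with exact path probabilities
  enumerate_chain <- function(K, s, p) {
    probs <- rep(0, K + 1)
    recurse <- function(k, step, weight) {
      if (step == s) {
        probs[k + 1] <<- probs[k + 1] + weight
        return()
      }
      p_new <- p * (K - k) / K
      if (p_new > 0) recurse(k + 1, step + 1, weight * p_new)
      recurse(k, step + 1, weight * (1 - p_new))
    }
    recurse(0, 0, 1)
    probs
  }
  pr <- build_adjacency_prior(S_max = 8, L = 2, dp_step = 0.01)
  tab <- prior_table(pr, 0.3)
  for (s in c(1, 4, 8)) {
    expect_equal(tab[, s + 1], enumerate_chain(6, s, 0.3), tolerance = 1e-12)
  }
})

test_that("real-count posterior matches the conditioned enumeration oracle", {
  pr <- build_adjacency_prior(S_max = 10, L = 2, dp_step = 0.01)  # K = 6
  expect_equal(real_count_distribution(0, 2, 5, 0.3, pr), 1)
  # p_adj ~ 0 clamps to the smallest quantization bin and favours zero real
  d0 <- real_count_distribution(3, 0, 6, 0, pr)
  expect_equal(which.max(d0), 1)
  expect_gt(d0[1], 0.9)
  # exhaustive oracle at K=6, S_g=5, N_L=1, N_S=2, p=0.2: distribution of
  # N' after S_g-1 picks, sliced at N' = n + N_L and renormalized
  enumerate_chain <- function(K, s, p) {
    probs <- rep(0, K + 1)
    recurse <- function(k, step, weight) {
      if (step == s) { probs[k + 1] <<- probs[k + 1] + weight; return() }
      p_new <- p * (K - k) / K
      if (p_new > 0) recurse(k + 1, step + 1, weight * p_new)
      recurse(k, step + 1, weight * (1 - p_new))
    }
    recurse(0, 0, 1)
    probs
  }
  chain <- enumerate_chain(6, 4, 0.2)
  oracle <- chain[1 + 1 + 0:2]  # N' = N_L + n for n = 0..N_S
  oracle <- oracle / sum(oracle)
  expect_equal(real_count_distribution(2, 1, 5, 0.2, pr), oracle, tolerance = 1e-12)
})

test_that("error-count distribution follows the cumulative binomial weights", {
  expect_error(error_count_distribution(1, 5, 1.2), "p_e")
  w <- error_count_distribution(1, 9, 0.1)
  raw <- c(dbinom(0, 9, 0.1), dbinom(1, 10, 0.1))
  expect_equal(w, raw / sum(raw))
  # three candidates, hand-computed
  r <- c(1, 1, 2)
  w3 <- error_count_distribution(r, 10, 0.15)
  cum <- c(0, cumsum(r))
  raw3 <- dbinom(cum, 10 + cum, 0.15)
  expect_equal(w3, raw3 / sum(raw3))
  # vanishing error rate concentrates on zero errors
  w0 <- error_count_distribution(c(1, 1), 10, 1e-9)
  expect_gt(w0[1], 1 - 1e-6)
})

test_that("collision occupancy matches brute-force enumeration", {
  pr <- build_adjacency_prior(S_max = 8, L = 4, dp_step = 0.01)  # K = 12
  expect_equal(collisions_among_errors(1, 1, pr), 1)
  expect_equal(collisions_among_errors(2, 2, dropcount::build_adjacency_prior(8, 2)), 5 / 6)
  expect_equal(collisions_among_errors(1, 2, dropcount::build_adjacency_prior(8, 2)), 1 / 6)
  # total = 4 events over K = 12 slots: enumerate all 12^4 outcomes
  outcomes <- as.matrix(expand.grid(1:12, 1:12, 1:12, 1:12))
  distinct <- apply(outcomes, 1, function(x) length(unique(x)))
  for (obs in 1:4) {
    expect_equal(collisions_among_errors(obs, 4, pr), mean(distinct == obs),
                 tolerance = 1e-12)
  }
})

test_that("nested posterior equals direct split evaluation and sane anchors", {
  qm <- toy_quality_model()
  pr <- build_adjacency_prior(S_max = 20, L = 4)
  g <- make_group(c("AAAA", "AAAT", "AATA", "TAAA", "GGGG"),
                  c(20, 3, 1, 25, 7),
                  quals = list(rep(35, 4), rep(12, 4), rep(15, 4), rep(35, 4), rep(30, 4)))
  v <- adjacent_umis("AAAA", g)
  expect_equal(v$n_s, 2)  # AAAT, AATA; TAAA has more reads
  post <- posterior_error_count(v, qm, pr, s_g = 5, p_adj = 0.1)
  direct <- vapply(0:v$n_s, function(j) {
    partition_probability(v, post$candidates$umi[seq_len(j)], qm, pr,
                          s_g = 5, p_adj = 0.1)
  }, numeric(1))
  expect_equal(post$posterior, direct / sum(direct), tolerance = 1e-12)
  expect_equal(sum(post$posterior), 1, tolerance = 1e-9)
  # no small-side neighbours: MAP is zero errors
  v_iso <- adjacent_umis("GGGG", g)
  expect_equal(posterior_error_count(v_iso, qm, pr, 5, 0.1)$map, 0)
  # an empty split scores 1 (empty products, degenerate distributions)
  g_iso <- make_group("CCCC", 5)
  v0 <- adjacent_umis("CCCC", g_iso)
  expect_equal(partition_probability(v0, character(), qm, pr, 1, 0.1), 1)
})

test_that("with uninformative quality the posterior is driven by reads and priors", {
  qm1 <- structure(list(support = 30, p_q = 1, p_q_err = 1, p_e = 0.05,
                        n_training_pairs = 5L), class = "umi_quality_model")
  pr <- build_adjacency_prior(S_max = 20, L = 4)
  g <- make_group(c("AAAA", "AAAT", "AATA"), c(50, 1, 2),
                  quals = list(rep(35, 4), rep(10, 4), rep(35, 4)))
  v <- adjacent_umis("AAAA", g)
  post <- posterior_error_count(v, qm1, pr, s_g = 3, p_adj = 0.01)
  # low-read candidates look erroneous even without quality information
  expect_gt(post$map, 0)
})

test_that("Bayesian filter removes an injected low-quality error and conserves reads", {
  # training pairs plus one target gene carrying the injected error
  rec <- dplyr::bind_rows(
    make_records("c1", c("GGGG", "GGGT"), "t1", c(9, 1),
                 quals = list(rep(35, 4), rep(10, 4))),
    make_records("c1", c("CCCC", "CCCA"), "t2", c(12, 2),
                 quals = list(rep(35, 4), rep(10, 4))),
    make_records("c1", c("TTTT", "TTTA"), "t3", c(7, 1),
                 quals = list(rep(35, 4), rep(10, 4))),
    make_records("c2", c("AAAA", "AAAT"), "g1", c(50, 1),
                 quals = list(rep(35, 4), rep(10, 4)))
  )
  out <- correct_umi_errors(rec, method = "bayesian")
  g1 <- out[out$gene == "g1", ]
  expect_equal(g1$umi, "AAAA")
  expect_equal(g1$reads, 51)
  expect_equal(sum(out$reads), sum(rec$reads))
  audit <- attr(out, "audit")
  expect_true("AAAT" %in% audit$removed_umi)
})

test_that("all filters are no-ops without Hamming-1 pairs and conserve reads", {
  set.seed(77)
  rec <- make_records(
    cb = "c1",
    umi = c("AAAA", "TTTT", "GGCC", "CCGG"),
    gene = "g1", reads = c(5, 3, 8, 2)
  )
  for (m in c("cluster", "cluster-neq", "directional")) {
    out <- correct_umi_errors(rec, method = m)
    expect_equal(sort(out$umi), sort(rec$umi))
  }
  # read conservation on a random error-laden fixture, all methods
  sim <- saturated_sim()
  total <- sum(sim$records$reads)
  for (out in saturated_corrections()) {
    expect_equal(sum(out$reads), total)
  }
})

test_that("iterative filtering converges quickly and never grows groups", {
  sim <- saturated_sim()
  corr <- saturated_corrections()[["bayesian"]]
  sizes_before <- dplyr::count(sim$records, cb, gene)
  sizes_after <- dplyr::count(corr, cb, gene)
  j <- dplyr::inner_join(sizes_before, sizes_after, by = c("cb", "gene"),
                         suffix = c("_before", "_after"))
  expect_true(all(j$n_after <= j$n_before))
  # a second application (with the same trained models) changes little:
  # the fixpoint is (near) stable
  qm <- train_quality_model(sim$records)
  dist <- estimate_umi_distribution(sim$records)
  corr2 <- correct_umi_errors(corr, method = "bayesian",
                              dist = dist, quality_model = qm)
  expect_lt(nrow(corr) - nrow(corr2), 0.02 * nrow(corr))
})
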