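# Omnigenic-model test battery: permutation enrichment, degree and
# coexpression tests, matching, effect-size comparison, trans-eQTL
# enrichment and neighbor enrichment.

test_that("overlap enrichment matches the hypergeometric oracle and floors p", {
  universe <- sprintf("g%04d", 1:1000)
  annotated <- universe[1:100]
  query <- universe[1:50]  # entirely inside the annotated set
  res <- overlap_enrichment(query, annotated, universe, n_perm = 2000, seed = 1)
  # hypergeometric expectation of the null overlap: 50 * 100/1000 = 5
  expect_lt(abs(res$null_mean - 5), 0.3)
  expect_lt(abs(res$fold_enrichment - 10), 0.7)
  expect_equal(res$p_value, 1 / 2001)  # at the add-one floor

  # saturation: annotated = universe
  sat <- overlap_enrichment(query, universe, universe, n_perm = 100, seed = 2)
  expect_equal(sat$fold_enrichment, 1)
  expect_equal(sat$p_value, 1)

  # determinism
  res2 <- overlap_enrichment(query, annotated, universe, n_perm = 2000, seed = 1)
  expect_identical(res$null, res2$null)
  expect_error(overlap_enrichment(character(0), annotated, universe), "non-empty")
  expect_error(overlap_enrichment("zz", annotated, universe), "subsets")
})

test_that("random-query enrichment is calibrated: FE near 1, uniform p", {
  universe <- sprintf("g%04d", 1:2000)
  annotated <- universe[1:400]
  stats <- t(vapply(1:150, function(s) {
    q <- with(list(), {set.seed(5000 + s); sample(universe, 100)})
    r <- overlap_enrichment(q, annotated, universe, n_perm = 400, seed = s)
    c(r$fold_enrichment, r$p_value)
  }, double(2)))
  expect_gt(mean(stats[, 1]), 0.95)
  expect_lt(mean(stats[, 1]), 1.05)
  expect_gt(suppressWarnings(ks.test(stats[, 2], "punif")$p.value), 0.01)
})

test_that("degree and coexpression tests detect the generator's core structure", {
  cfg <- network_sim_config(250, 20, base_degree = 5, core_degree_multiplier = 5,
                            core_mutual_correlation = 0.3, seed = 14)
  net <- simulate_network(cfg)
  core <- net$flags$gene[net$flags$core]
  dt <- degree_test(net, core, 0.2)
  expect_lt(dt$p_value, 0.01)
  ct <- core_coexpression_test(net, core, n_perm = 2000, seed = 3)
  expect_lt(ct$p_value, 0.01)
  expect_gt(ct$observed, ct$null_mean)

  # cutoff above every correlation: degenerate, flagged, p = 1
  expect_warning(dt0 <- degree_test(net, core, 0.999), "zero")
  expect_equal(dt0$p_value, 1)
  expect_true(dt0$degenerate)
  expect_error(degree_test(net, "nope", 0.2), "no core genes")
  expect_error(core_coexpression_test(net, core[1]), "at least 2")
})

test_that("greedy matching honours cardinality, determinism and closeness", {
  set.seed(21)
  maf <- c(rep(0.01, 10), runif(200, 0.005, 0.5))
  treated <- c(rep(TRUE, 10), rep(FALSE, 200))
  m1 <- match_nearest(maf, treated, ratio = 1)
  expect_equal(nrow(m1), 10L)
  expect_false(anyDuplicated(m1$control_index) > 0)
  # matched controls cluster near the treated MAF
  expect_lt(median(abs(maf[m1$control_index] - 0.01)), 0.02)
  # balance post-check on a non-degenerate fixture
  maf2 <- c(runif(40, 0.01, 0.3), runif(300, 0.005, 0.5))
  tr2 <- c(rep(TRUE, 40), rep(FALSE, 300))
  mb <- match_nearest(maf2, tr2)
  expect_gt(wilcox.test(maf2[mb$treated_index], maf2[mb$control_index])$p.value,
            0.05)

  m2 <- match_nearest(maf, treated, ratio = 2)
  expect_equal(nrow(m2), 20L)
  expect_false(anyDuplicated(m2$control_index) > 0)

  # identical controls give zero distances
  vals <- c(1, 2, 3, 1, 2, 3)
  tr <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  m3 <- match_nearest(vals, tr)
  expect_equal(m3$distance, rep(0, 3))
  expect_identical(match_nearest(maf, treated), match_nearest(maf, treated))
  expect_error(match_nearest(1:3, c(TRUE, TRUE, FALSE), ratio = 2),
               "insufficient controls")
})

test_that("matched effect comparison: null FC near 1, doubled betas near 2", {
  gen <- function(seed, fold) {
    set.seed(seed)
    n_core <- 60; n_ctrl <- 300
    maf <- c(runif(n_core, 0.01, 0.5), runif(n_ctrl, 0.01, 0.5))
    beta <- rlnorm(n_core + n_ctrl, log(0.05), 0.4)
    beta[seq_len(n_core)] <- beta[seq_len(n_core)] * fold
    tibble::tibble(abs_beta = beta, maf = maf, class = "missense",
                   core = c(rep(TRUE, n_core), rep(FALSE, n_ctrl)))
  }
  null_fc <- vapply(1:10, function(s) {
    matched_effect_comparison(gen(s, 1))$fold_change
  }, double(1))
  expect_lt(abs(mean(null_fc) - 1), 0.15)

  dbl_fc <- vapply(1:10, function(s) {
    r <- matched_effect_comparison(gen(100 + s, 2))
    expect_lt(r$p_value, 0.01)
    r$fold_change
  }, double(1))
  expect_gt(mean(dbl_fc), 1.8)
  expect_lt(mean(dbl_fc), 2.2)

  # classes under the 10-variant floor are skipped with a log entry
  small <- gen(3, 2)[c(1:9, 61:80), ]
  big <- gen(4, 2); big$class <- "synonymous"
  expect_message(out <- matched_effect_comparison(dplyr::bind_rows(small, big)),
                 "skipped")
  expect_equal(out$class, "synonymous")
  expect_equal(attr(out, "skipped_classes"), "missense")
  expect_error(matched_effect_comparison(small), "no annotation class")
})

test_that("trans-eQTL enrichment recovers the generator's fold", {
  net <- simulate_network(network_sim_config(250, 20, base_degree = 5, seed = 31))
  core <- net$flags$gene[net$flags$core]
  te <- simulate_trans_eqtls(net, enrichment = 2, n_eqtls = 5000, seed = 32)
  res <- trans_eqtl_enrichment(te$eqtls, core, te$expression)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$fold, 1.5)

  t0 <- simulate_trans_eqtls(net, enrichment = 1, n_eqtls = 5000, seed = 33)
  r0 <- trans_eqtl_enrichment(t0$eqtls, core, t0$expression)
  expect_lt(abs(r0$fold - 1), 0.35)

  one <- tibble::tibble(gene = rep("G0001", 50), z = rnorm(50, 6))
  expect_error(trans_eqtl_enrichment(one, core, te$expression), "degenerate")
})

test_that("neighbor enrichment: monotone neighborhoods and constructed signal", {
  net <- simulate_network(network_sim_config(200, 15, base_degree = 6,
                                             core_degree_multiplier = 4,
                                             core_mutual_correlation = 0.3,
                                             seed = 41))
  core <- net$flags$gene[net$flags$core]
  n1 <- attr(neighbor_enrichment(net, core, core, degree = 1, cutoff = 0.2,
                                 n_perm = 200, seed = 1), "neighbors")
  n2 <- attr(neighbor_enrichment(net, core, core, degree = 2, cutoff = 0.2,
                                 n_perm = 200, seed = 1), "neighbors")
  expect_true(all(n1 %in% n2))

  # query concentrated in first-degree neighbors: p at the floor
  query <- n1[seq_len(min(30, length(n1)))]
  res <- neighbor_enrichment(net, core, query, degree = 1, cutoff = 0.2,
                             n_perm = 1000, seed = 2)
  expect_equal(res$p_value, 1 / 1001)
  # query = universe saturates FE at 1
  sat <- neighbor_enrichment(net, core, net$flags$gene, degree = 1,
                             cutoff = 0.2, n_perm = 100, seed = 3)
  expect_equal(sat$fold_enrichment, 1)
  expect_error(neighbor_enrichment(net, core, query, degree = 3, cutoff = 0.2),
               "degree")
  expect_error(neighbor_enrichment(net, core, query, degree = 1, cutoff = 0.99),
               "empty")
})
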