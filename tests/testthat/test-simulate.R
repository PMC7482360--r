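# Synthetic-cohort generators: determinism, dosage domains, LD structure,
# variance decomposition, network and eQTL structure, disease calibration.

test_that("genotype generator is deterministic and respects the dosage domain", {
  cfg <- sim_config(n_samples = 4, n_variants = 1, maf_range = c(0.5, 0.5), seed = 1)
  G <- simulate_genotypes(cfg)
  expect_equal(dim(G), c(4L, 1L))
  expect_true(all(G$dosages %in% c(0, 1, 2)))

  cfg2 <- sim_config(n_samples = 300, n_variants = 40, ld_block_span = 8, seed = 9)
  expect_identical(simulate_genotypes(cfg2)$dosages,
                   simulate_genotypes(cfg2)$dosages)

  cfgd <- sim_config(n_samples = 500, n_variants = 20, mode = "dosage", seed = 3)
  Gd <- simulate_genotypes(cfgd)
  expect_true(all(Gd$dosages >= 0 & Gd$dosages <= 2))
  expect_true(all(Gd$variants$info >= 0 & Gd$variants$info <= 1))
  expect_true(mean(Gd$variants$info) < 1)  # noise visibly degrades INFO
})

test_that("sim_config rejects invalid inputs", {
  expect_error(sim_config(0, 10), "n_samples")
  expect_error(sim_config(10, 10, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(10, 10, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(10, 10, causal_spec = data.frame(index = c(1, 1), beta = 1)),
               "unique")
  expect_error(sim_config(10, 10, causal_spec = data.frame(index = 11, beta = 1)),
               "within")
})

test_that("ld_block_span = 1 gives independent variants; blocks carry LD", {
  # Monte-Carlo mean off-diagonal r^2 under independence is ~ 1/n
  n <- 300
  r2_ind <- replicate(40, {
    G <- simulate_genotypes(sim_config(n, 12, ld_block_span = 1,
                                       maf_range = c(0.2, 0.5),
                                       seed = sample.int(1e6, 1)))
    cc <- suppressWarnings(cor(G$dosages)^2)  # rare monomorphic draws give NA
    mean(cc[upper.tri(cc)], na.rm = TRUE)
  })
  expect_lt(abs(mean(r2_ind) - 1 / n), 3 / n)

  G <- simulate_genotypes(sim_config(2000, 20, ld_block_span = 10, seed = 5))
  cc <- cor(G$dosages)^2
  within <- mean(cc[1:10, 1:10][upper.tri(cc[1:10, 1:10])])
  across <- mean(cc[1:10, 11:20])
  expect_gt(within, 10 * across)
  expect_gt(within, 0.05)
})

test_that("realized MAF stays inside the configured range up to sampling error", {
  G <- simulate_genotypes(sim_config(3000, 60, ld_block_span = 6,
                                     maf_range = c(0.1, 0.4), seed = 11))
  maf <- pmin(G$variants$eaf, 1 - G$variants$eaf)
  # the 20-founder pool adds binomial noise around the target spectrum
  expect_true(all(maf >= 0 & maf <= 0.5))
  expect_gt(mean(maf >= 0.05 & maf <= 0.45), 0.8)
  expect_lt(abs(mean(maf) - 0.25), 0.05)
})

test_that("pure-noise phenotype is standard normal and null p-values are uniform", {
  cc <- make_cohort(10000, 5, seed = 21)
  expect_gt(var(cc$y$phenotype), 0.9)
  expect_lt(var(cc$y$phenotype), 1.1)

  cc2 <- make_cohort(2000, 400, seed = 22)
  ss <- single_variant_scan(cc2$G, cc2$y$phenotype)
  expect_gt(ks.test(ss$p, "punif")$p.value, 0.01)
})

test_that("sparse causal effects are recovered by OLS within 2 SE", {
  causal <- data.frame(index = 3, beta = 0.5)
  cc <- make_cohort(4000, 10, seed = 31, causal = causal)
  g <- cc$G$dosages[, 3]
  fit <- summary(lm(cc$y$phenotype ~ g))
  expect_lt(abs(fit$coefficients[2, 1] - 0.5), 2 * fit$coefficients[2, 2])
})

test_that("variance budget is enforced and polygenic fraction is calibrated", {
  expect_error(
    simulate_phenotype(
      simulate_genotypes(sim_config(200, 5, seed = 1)),
      sim_config(200, 5, seed = 1,
                 causal_spec = data.frame(index = 1:3, beta = c(1, 1, 1)))
    ),
    "variance budget"
  )
  fracs <- vapply(1:25, function(s) {
    cc <- make_cohort(1500, 50, seed = 100 + s, h2 = 0.3)
    var(attr(cc$y, "truth")$polygenic_component)
  }, double(1))
  expect_lt(abs(mean(fracs) - 0.3), 0.02)
})

test_that("covariate effects enter the phenotype and stay inside the budget", {
  cfg <- sim_config(3000, 5, seed = 41,
                    covariate_effects = list(age = 0.02, sex = 0.3, pc = c(0.1, 0)))
  G <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(G, cfg)
  fit <- summary(lm(phenotype ~ age + sex + pc1, data = ph))
  expect_lt(abs(fit$coefficients["sex", 1] - 0.3), 2.5 * fit$coefficients["sex", 2])
  expect_lt(abs(var(ph$phenotype) - 1), 0.12)
})

test_that("network generator: diagonal, symmetry, PSD, and degree structure", {
  cfg <- network_sim_config(150, 15, base_degree = 5, core_degree_multiplier = 5,
                            core_mutual_correlation = 0.3, seed = 6)
  net <- simulate_network(cfg)
  R <- net$correlation
  expect_equal(unname(diag(R)), rep(1, 150))
  expect_true(isSymmetric(unname(R)))
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-6)
  deg <- network_degrees(net, 0.2)
  expect_gt(mean(deg$degree[deg$core]), mean(deg$degree[!deg$core]))
  # degree monotone non-increasing in cutoff
  d2 <- network_degrees(net, 0.4)
  expect_true(all(d2$degree <= deg$degree))
})

test_that("null network configuration equalises core and non-core degrees", {
  pvals <- vapply(1:20, function(s) {
    net <- simulate_network(network_sim_config(
      120, 12, base_degree = 5, core_degree_multiplier = 1,
      core_mutual_correlation = 0, seed = 600 + s
    ))
    core <- net$flags$gene[net$flags$core]
    degree_test(net, core, 0.2)$p_value
  }, double(1))
  # exchangeable labels: p should not pile up near 0
  expect_length(pvals, 20L)
  expect_lt(mean(pvals < 0.05), 0.35)
})

test_that("trans-eQTL generator: integrity, null, and enrichment ratio", {
  net <- simulate_network(network_sim_config(200, 20, base_degree = 5, seed = 8))
  te <- simulate_trans_eqtls(net, enrichment = 2, n_eqtls = 5000, seed = 9)
  expect_true(all(te$eqtls$gene %in% net$flags$gene))
  expect_equal(nrow(te$eqtls), 5000)

  ratios <- vapply(1:15, function(s) {
    tt <- simulate_trans_eqtls(net, enrichment = 2, n_eqtls = 5000, seed = 900 + s)
    counts <- table(factor(tt$eqtls$gene, levels = net$flags$gene))
    mean(counts[net$flags$core]) / mean(counts[!net$flags$core])
  }, double(1))
  expect_gt(mean(ratios), 1.7)
  expect_lt(mean(ratios), 2.3)

  t0 <- simulate_trans_eqtls(net, enrichment = 1, n_eqtls = 3000, seed = 10)
  counts <- table(factor(t0$eqtls$gene, levels = net$flags$gene))
  p <- wilcox.test(as.numeric(counts[net$flags$core]),
                   as.numeric(counts[!net$flags$core]))$p.value
  expect_gt(p, 0.001)
})

test_that("disease generator calibrates prevalence and odds ratio", {
  set.seed(1)
  pgs <- rnorm(20000)
  lab <- simulate_disease(pgs, or_per_sd = 1.5, prevalence = 0.05, seed = 2)
  expect_gt(mean(lab), 0.04)
  expect_lt(mean(lab), 0.06)
  fit <- glm(lab ~ pgs, family = binomial())
  expect_lt(abs(exp(coef(fit)[2]) - 1.5), 0.12)

  # null: slope z-score small in most seeds
  zs <- vapply(1:20, function(s) {
    lb <- simulate_disease(pgs, or_per_sd = 1, prevalence = 0.05, seed = 100 + s)
    summary(glm(lb ~ pgs, family = binomial()))$coefficients[2, 3]
  }, double(1))
  expect_gt(mean(abs(zs) < 3), 0.9)
})
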