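# Polygenic scores: selection strategies, scoring, evaluation, disease
# models, carrier penetrance and deviation checks.

pgs_stats <- function(G, y) single_variant_scan(G, y)

test_that("selection strategies behave per contract", {
  causal <- data.frame(index = c(3, 12, 21), beta = c(0.3, 0.25, 0.2))
  cc <- make_cohort(3000, 30, seed = 201, span = 3, causal = causal)
  ss <- pgs_stats(cc$G, cc$y$phenotype)
  sent <- stepwise_select(cc$G, cc$y$phenotype, p_threshold = 1e-6)

  d <- select_variants(ss, "d", sentinels = sent)
  expect_equal(nrow(d), nrow(sent))
  expect_true(all(d$weight >= 0))
  expect_false(anyDuplicated(d$id) > 0)

  fmp <- tibble::tibble(variant = ss$id[1], pip = 0.9)
  cmod <- select_variants(ss, "c", sentinels = sent, finemap_pip = fmp)
  expect_true(ss$id[1] %in% cmod$id)
  expect_true(all(sent$id %in% cmod$id))

  a <- select_variants(ss, "a", G = cc$G)
  # pruning keeps at most one of any r2 > 0.8 pair
  R2 <- cor(cc$G$dosages[, a$id])^2
  expect_true(all(R2[upper.tri(R2)] <= 0.8))

  b <- select_variants(ss, "b", G = cc$G, p_threshold = 1e-4)
  expect_true(all(ss$p[match(b$id, ss$id)] < 1e-4))
  expect_error(select_variants(ss, "b", G = cc$G, p_threshold = 1e-300),
               "no variants selected")
  expect_error(select_variants(ss, "c", sentinels = sent), "fine-map")
  expect_error(select_variants(ss, "a"), "LD reference")
})

test_that("pruning keeps exactly one of a perfectly correlated pair", {
  set.seed(7)
  g <- rbinom(500, 2, 0.4)
  X <- cbind(v1 = g, v2 = g, v3 = rbinom(500, 2, 0.4))
  stats <- tibble::tibble(id = c("v1", "v2", "v3"),
                          effect_allele = "A", other_allele = "G",
                          beta = c(0.5, 0.5, 0.2), p = c(1e-10, 1e-9, 1e-4))
  pruned <- hemegwas:::ld_prune(stats, X, r2 = 0.8)
  expect_equal(pruned$id, c("v1", "v3"))
})

test_that("scoring is linear, orientation-invariant and standardized", {
  cc <- make_cohort(1000, 5, seed = 211)
  v <- cc$G$variants
  model <- tibble::tibble(id = v$id[2], effect_allele = v$alt[2], weight = 1)
  sc <- compute_pgs(cc$G, model)
  expect_equal(abs(cor(sc, cc$G$dosages[, 2])), 1)
  expect_lt(abs(mean(sc)), 1e-12)
  expect_equal(sd(sc), 1, tolerance = 1e-12)

  # flipping allele label together with orientation leaves scores unchanged
  flipped <- tibble::tibble(id = v$id[2], effect_allele = v$ref[2], weight = 1)
  sc2 <- compute_pgs(cc$G, flipped)
  expect_equal(sc2, -sc, ignore_attr = TRUE)  # reflected dosage reverses sign...
  # ...but a weight built from a negative beta restores identity:
  ss <- tibble::tibble(id = v$id[2], effect_allele = v$alt[2],
                       other_allele = v$ref[2], beta = -0.4, p = 1e-9)
  m2 <- select_variants(ss, "d", sentinels = tibble::tibble(id = v$id[2]))
  expect_equal(m2$effect_allele, v$ref[2])
  expect_equal(compute_pgs(cc$G, m2), -compute_pgs(
    cc$G, tibble::tibble(id = v$id[2], effect_allele = v$alt[2], weight = 0.4)
  ), ignore_attr = TRUE)

  zero <- tibble::tibble(id = v$id[1:2], effect_allele = v$alt[1:2], weight = 0)
  expect_error(compute_pgs(cc$G, zero), "zero score variance")
  absent <- tibble::tibble(id = "9:9_A_G", effect_allele = "G", weight = 1)
  expect_error(compute_pgs(cc$G, absent), "absent")

  # missing dosages are mean-imputed
  G2 <- cc$G
  G2$dosages[1:10, 2] <- NA
  expect_silent(sc3 <- compute_pgs(G2, model))
  expect_equal(length(sc3), 1000L)
})

test_that("evaluation returns R and R^2 with sane null behaviour", {
  set.seed(31)
  x <- rnorm(5000)
  expect_equal(evaluate_pgs(x, x)$r_squared, 1)
  nulls <- vapply(1:30, function(s) {
    set.seed(s); abs(cor(rnorm(5000), rnorm(5000)))
  }, double(1))
  expect_gt(mean(nulls < 0.05), 0.95)
  expect_error(evaluate_pgs(x, rep(1, 5000)), "constant")
})

test_that("standardization invariance: affine raw-score transforms change nothing", {
  cc <- make_cohort(2000, 10, seed = 221,
                    causal = data.frame(index = 1:3, beta = c(0.2, 0.2, 0.2)))
  v <- cc$G$variants
  model <- tibble::tibble(id = v$id[1:3], effect_allele = v$alt[1:3],
                          weight = c(0.2, 0.2, 0.2))
  scaled <- dplyr::mutate(model, weight = weight * 7)  # affine raw transform
  s1 <- compute_pgs(cc$G, model)
  s2 <- compute_pgs(cc$G, scaled)
  expect_equal(s1, s2, ignore_attr = TRUE, tolerance = 1e-12)
  e1 <- evaluate_pgs(s1, cc$y$phenotype)
  e2 <- evaluate_pgs(s2, cc$y$phenotype)
  expect_equal(e1$r, e2$r)
})

test_that("disease association enforces the case floor and recovers the OR", {
  set.seed(41)
  pgs <- rnorm(20000)
  lab <- simulate_disease(pgs, or_per_sd = 1.5, prevalence = 0.05, seed = 42)
  fit <- pgs_disease_association(pgs, lab)
  expect_gt(fit$or_per_sd, 1.35)
  expect_lt(fit$or_per_sd, 1.67)
  expect_lt(fit$p_value, 1e-10)

  few <- c(rep(1, 39), rep(0, 1000))
  expect_error(pgs_disease_association(rnorm(1039), few), "at least 40")

  # separation is refused with a diagnostic
  xx <- c(rnorm(50, 10), rnorm(500, -10))
  yy <- c(rep(1, 50), rep(0, 500))
  expect_error(pgs_disease_association(xx, yy), "separation")

  # null coverage: CI covers 1 in most seeds
  cover <- vapply(1:20, function(s) {
    lb <- simulate_disease(pgs, or_per_sd = 1, prevalence = 0.05, seed = 500 + s)
    ci <- pgs_disease_association(pgs, lb)
    ci$ci_lower <= 1 && ci$ci_upper >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("multi-disease scan applies Bonferroni and skips small diseases", {
  set.seed(51)
  pgs <- rnorm(8000)
  labs <- list(
    d1 = simulate_disease(pgs, 1.4, 0.05, seed = 1),
    d2 = simulate_disease(pgs, 1.0, 0.05, seed = 2),
    tiny = c(rep(1L, 10), rep(0L, 7990))
  )
  out <- pgs_disease_scan(pgs, labs)
  expect_equal(out$disease, c("d1", "d2"))
  expect_equal(attr(out, "skipped"), "tiny")
  expect_equal(out$p_bonferroni, pmin(out$p_value * 2, 1))
})

test_that("carrier penetrance matches the cross-product oracle", {
  # 2x2 table (a=10, b=90, c=5, d=195): OR = 10*195/(90*5)
  carrier <- c(rep(TRUE, 100), rep(FALSE, 200))
  trait <- c(rep(100, 10), rep(200, 90), rep(100, 5), rep(200, 195))
  res <- carrier_penetrance(carrier, trait, bound = 150, direction = "below")
  expect_equal(res$odds_ratio, 10 * 195 / (90 * 5), tolerance = 1e-12)
  expect_false(res$corrected)
  # equals the covariate-free logistic OR
  fit <- glm(I(trait < 150) ~ carrier, family = binomial())
  expect_equal(res$odds_ratio, unname(exp(coef(fit)[2])), tolerance = 1e-6)

  # zero cell: finite OR via the 0.5 correction, flagged
  z <- carrier_penetrance(c(rep(TRUE, 5), rep(FALSE, 100)),
                          c(rep(200, 5), rep(100, 50), rep(200, 50)),
                          bound = 150)
  expect_true(z$corrected)
  expect_true(is.finite(z$odds_ratio))

  # null: CI covers 1
  set.seed(61)
  tr <- rnorm(2000, 200, 30)
  cr <- rep(c(TRUE, FALSE), 1000)
  r0 <- carrier_penetrance(cr, tr, bound = 150)
  expect_true(r0$ci_lower <= 1 && r0$ci_upper >= 1)
  expect_error(carrier_penetrance(rep(TRUE, 5), rnorm(5), 0), "non-carriers")
})

test_that("PGS deviation check: tail rate, flags and branch selection", {
  set.seed(71)
  pop <- rnorm(50000)
  res <- pgs_deviation_check(rnorm(5000), pop, k = 2)
  expect_lt(abs(res$flag_rate - 2 * pnorm(-2)), 0.01)
  expect_equal(res$branch, "logistic")

  hi <- pgs_deviation_check(c(3, 0.1), pop, k = 2)
  expect_equal(hi$flags, c(TRUE, FALSE))
  expect_equal(hi$branch, "threshold")

  expect_equal(pgs_deviation_check(rnorm(11), pop)$branch, "logistic")
  expect_equal(pgs_deviation_check(rnorm(9), pop)$branch, "threshold")
  expect_error(pgs_deviation_check(numeric(0), pop), "empty")
})
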