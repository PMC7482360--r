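# Polygenic scores: variant selection strategies, weighted-sum scoring,
# variance explained, disease logistic models, carrier penetrance and the
# PGS-deviation check for rare-variant carriers.

# Greedy LD pruning: keep variants in ascending-p order, discarding any
# candidate with r^2 above `r2` with an already kept variant.
ld_prune <- function(stats, X, r2 = 0.8) {
  ord <- order(stats$p)
  kept <- integer(0)
  for (i in ord) {
    id <- stats$id[i]
    if (!id %in% colnames(X)) abort(sprintf("variant %s absent from the LD reference.", id))
    if (length(kept) == 0) {
      kept <- i
      next
    }
    rr <- as.vector(cor(X[, id], X[, stats$id[kept], drop = FALSE]))^2
    if (all(rr <= r2, na.rm = TRUE)) kept <- c(kept, i)
  }
  stats[sort(kept), , drop = FALSE]
}

#' Select variants and weights for a polygenic score
#'
#' Implements the four selection strategies compared in blood-trait PGS
#' construction: (a) all genome-wide variants after LD pruning at r^2 0.8;
#' (b) LD-pruned variants passing a GWAS p-value threshold (conventionally
#' one of 0.05, 5e-4, 5e-6, 5e-8); (c) conditionally independent sentinel
#' variants plus fine-mapped variants with posterior inclusion probability
#' above 0.5; (d) conditionally independent sentinel variants only. Weights
#' are the GWAS effect sizes oriented to trait-increasing alleles, so every
#' stored weight is non-negative.
#'
#' @param stats Summary statistics tibble (`id`, `effect_allele`,
#'   `other_allele`, `beta`, `p`).
#' @param strategy One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param G LD reference [geno_matrix()] (required for strategies a and b).
#' @param p_threshold GWAS p-value threshold (strategy b).
#' @param sentinels `sentinel_set` or tibble with `id` (strategies c, d);
#'   its `beta` column, when present, supplies the joint-model weights.
#' @param finemap_pip Tibble with `variant` and `pip` columns (strategy c),
#'   e.g. the `pip` element of a `finemap_result`.
#' @param pip_min PIP cutoff for strategy c.
#' @param prune_r2 LD pruning cutoff for strategies a and b.
#' @return A `pgs_model` tibble: `id`, `effect_allele`, `weight` (all
#'   `>= 0`), with attribute `strategy`.
#' @export
select_variants <- function(stats, strategy = c("a", "b", "c", "d"), G = NULL,
                            p_threshold = NULL, sentinels = NULL,
                            finemap_pip = NULL, pip_min = 0.5,
                            prune_r2 = 0.8) {
  strategy <- match.arg(strategy)
  stats <- tibble::as_tibble(stats)
  need <- c("id", "effect_allele", "other_allele", "beta", "p")
  miss <- setdiff(need, names(stats))
  if (length(miss) > 0) abort(sprintf("missing column(s): %s.", paste(miss, collapse = ", ")))

  picked <- switch(
    strategy,
    a = {
      if (is.null(G)) abort("strategy a requires an LD reference `G`.")
      ld_prune(stats, as_dosage_matrix(G), r2 = prune_r2)
    },
    b = {
      if (is.null(G)) abort("strategy b requires an LD reference `G`.")
      if (is.null(p_threshold)) abort("strategy b requires `p_threshold`.")
      sub <- stats[stats$p < p_threshold, , drop = FALSE]
      if (nrow(sub) == 0) abort("no variants selected at this p-value threshold.")
      ld_prune(sub, as_dosage_matrix(G), r2 = prune_r2)
    },
    c = {
      if (is.null(sentinels)) abort("strategy c requires `sentinels`.")
      if (is.null(finemap_pip)) abort("strategy c requires fine-mapping input `finemap_pip`.")
      fm_ids <- finemap_pip$variant[finemap_pip$pip > pip_min]
      ids <- union(sentinels$id, fm_ids)
      stats[stats$id %in% ids, , drop = FALSE]
    },
    d = {
      if (is.null(sentinels)) abort("strategy d requires `sentinels`.")
      stats[stats$id %in% sentinels$id, , drop = FALSE]
    }
  )
  if (nrow(picked) == 0) abort("no variants selected.")
  # sentinel joint-model betas take precedence over marginal betas
  if (strategy %in% c("c", "d") && !is.null(sentinels) && "beta" %in% names(sentinels)) {
    j <- match(picked$id, sentinels$id)
    picked$beta <- ifelse(is.na(j), picked$beta, sentinels$beta[j])
  }
  picked <- picked[!duplicated(picked$id), , drop = FALSE]
  flip <- picked$beta < 0
  model <- tibble::tibble(
    id = picked$id,
    effect_allele = ifelse(flip, picked$other_allele, picked$effect_allele),
    weight = abs(picked$beta)
  )
  attr(model, "strategy") <- strategy
  class(model) <- c("pgs_model", class(model))
  model
}

#' Compute a standardized polygenic score
#'
#' The raw score of each sample is the weighted sum over model variants of
#' the dosage of the (trait-increasing) effect allele; dosages of variants
#' stored on the opposite allele are reflected as `2 - dosage`. Missing
#' dosage entries are mean-imputed from the sample effect-allele frequency.
#' The score is standardized to mean 0, SD 1 over the sample.
#'
#' @param G A [geno_matrix()] containing every model variant.
#' @param model A `pgs_model` from [select_variants()], or a tibble with
#'   `id`, `effect_allele`, `weight`.
#' @return Numeric standardized score vector; attribute `raw` holds the
#'   unstandardized scores.
#' @export
compute_pgs <- function(G, model) {
  stopifnot(inherits(G, "geno_matrix"))
  model <- tibble::as_tibble(model)
  j <- match(model$id, G$variants$id)
  if (anyNA(j)) {
    abort(sprintf("model variant(s) absent from `G`: %s.",
                  paste(model$id[is.na(j)], collapse = ", ")))
  }
  X <- G$dosages[, j, drop = FALSE]
  # mean-impute missing entries from the realized allele frequency
  if (anyNA(X)) {
    for (k in seq_len(ncol(X))) {
      nas <- is.na(X[, k])
      if (any(nas)) X[nas, k] <- mean(X[!nas, k])
    }
  }
  alt <- G$variants$alt[j]; ref <- G$variants$ref[j]
  on_alt <- model$effect_allele == alt
  on_ref <- model$effect_allele == ref
  if (!all(on_alt | on_ref)) {
    abort("model effect alleles do not match the genotype alleles.")
  }
  D <- X
  D[, on_ref] <- 2 - D[, on_ref, drop = FALSE]
  raw <- as.vector(D %*% model$weight)
  if (sd(raw) < 1e-12) abort("zero score variance.")
  out <- as.vector(scale(raw))
  attr(out, "raw") <- raw
  out
}

#' Evaluate a polygenic score against its phenotype
#'
#' @param scores Standardized score vector.
#' @param phenotype Phenotype vector aligned with `scores`.
#' @return Tibble `r` (Pearson correlation), `r_squared` (variance
#'   explained), `n`.
#' @export
evaluate_pgs <- function(scores, phenotype) {
  if (length(scores) != length(phenotype)) abort("inputs must be aligned.")
  ok <- complete.cases(scores, phenotype)
  if (sum(ok) < 3) abort("need at least 3 paired observations.")
  if (sd(scores[ok]) < 1e-12 || sd(phenotype[ok]) < 1e-12) abort("constant input.")
  r <- cor(scores[ok], phenotype[ok])
  tibble::tibble(r = r, r_squared = r^2, n = sum(ok))
}

#' Logistic association of a polygenic score with disease status
#'
#' Fits `status ~ PGS + covariates` by logistic regression and reports the
#' odds ratio per SD of the (standardized) score with a Wald 95% confidence
#' interval. Diseases with fewer than `min_cases` cases are refused, and
#' fits showing separation are refused with a diagnostic.
#'
#' @param scores Standardized score vector.
#' @param labels 0/1 disease status vector.
#' @param covariates Optional data frame of covariates (e.g. sex, age,
#'   principal components).
#' @param min_cases Minimum number of cases (default 40).
#' @return Tibble `or_per_sd`, `ci_lower`, `ci_upper`, `p_value`,
#'   `n_cases`, `n`.
#' @export
pgs_disease_association <- function(scores, labels, covariates = NULL,
                                    min_cases = 40L) {
  n_cases <- sum(labels == 1)
  if (n_cases < min_cases) {
    abort(sprintf("only %d cases; at least %d required.", n_cases, min_cases))
  }
  df <- data.frame(.y = labels, .pgs = scores)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  cf <- summary(fit)$coefficients
  b <- cf[".pgs", "Estimate"]; se <- cf[".pgs", "Std. Error"]
  if (!fit$converged || abs(b) > 15 || se > 100) {
    abort("logistic fit shows separation or non-convergence; association refused.")
  }
  tibble::tibble(
    or_per_sd = exp(b),
    ci_lower = exp(b - 1.96 * se), ci_upper = exp(b + 1.96 * se),
    p_value = cf[".pgs", "Pr(>|z|)"], n_cases = n_cases, n = length(labels)
  )
}

#' Polygenic score association across several diseases
#'
#' Runs [pgs_disease_association()] for each disease label vector and
#' applies a Bonferroni correction across the diseases tested. Diseases
#' failing the case floor are reported as skipped rather than fitted.
#'
#' @param scores Standardized score vector.
#' @param labels_list Named list of 0/1 label vectors, one per disease.
#' @param covariates Optional covariate data frame shared by all fits.
#' @param min_cases Case floor per disease.
#' @return Tibble with one row per tested disease, including
#'   `p_bonferroni`; attribute `skipped` names diseases under the case
#'   floor.
#' @export
pgs_disease_scan <- function(scores, labels_list, covariates = NULL,
                             min_cases = 40L) {
  if (is.null(names(labels_list))) abort("`labels_list` must be named by disease.")
  fits <- list(); skipped <- character(0)
  for (dz in names(labels_list)) {
    lab <- labels_list[[dz]]
    if (sum(lab == 1) < min_cases) {
      skipped <- c(skipped, dz)
      next
    }
    fits[[dz]] <- dplyr::mutate(
      pgs_disease_association(scores, lab, covariates, min_cases),
      disease = dz, .before = 1
    )
  }
  if (length(fits) == 0) abort("no disease passed the case floor.")
  out <- dplyr::bind_rows(fits)
  out$p_bonferroni <- pmin(out$p_value * nrow(out), 1)
  attr(out, "skipped") <- skipped
  out
}

#' Carrier penetrance odds ratio from a 2x2 table
#'
#' Cross-tabulates carrier status against having a blood index outside the
#' normal range (below or above a clinical bound) and reports the
#' cross-product odds ratio with a Woolf confidence interval. When any cell
#' is zero, the Haldane-Anscombe 0.5 correction is applied and flagged.
#'
#' @param carrier Logical carrier flags.
#' @param trait Trait values aligned with `carrier`.
#' @param bound Clinical normal-range bound (e.g. platelets 150 x 10^9/L).
#' @param direction `"below"` if values under the bound are outside the
#'   normal range, `"above"` otherwise.
#' @return Tibble `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`,
#'   `corrected` plus the four cell counts.
#' @export
carrier_penetrance <- function(carrier, trait, bound,
                               direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (!is.logical(carrier) || length(carrier) != length(trait)) {
    abort("`carrier` must be a logical vector aligned with `trait`.")
  }
  if (all(carrier) || !any(carrier)) abort("need both carriers and non-carriers.")
  outside <- if (direction == "below") trait < bound else trait > bound
  a <- sum(carrier & outside); b <- sum(carrier & !outside)
  cc <- sum(!carrier & outside); d <- sum(!carrier & !outside)
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- log(or) / se
  tibble::tibble(
    odds_ratio = or, ci_lower = exp(log(or) - 1.96 * se),
    ci_upper = exp(log(or) + 1.96 * se), p_value = 2 * pnorm(-abs(z)),
    corrected = corrected,
    n_carrier_outside = sum(carrier & outside),
    n_carrier_inside = sum(carrier & !outside),
    n_noncarrier_outside = sum(!carrier & outside),
    n_noncarrier_inside = sum(!carrier & !outside)
  )
}

#' Polygenic-score deviation check for rare-variant carriers
#'
#' Flags carriers whose polygenic score deviates from the population mean
#' by more than `k` population SDs. With more than 10 carriers, a logistic
#' regression of carrier status on the score provides the group-level test;
#' with 10 or fewer, only the threshold flags and a binomial test against
#' the normal-tail expectation `2 * pnorm(-k)` are reported.
#'
#' @param carrier_scores Scores of the carriers.
#' @param population_scores Standardized scores of the population.
#' @param k Deviation threshold in population SDs (default 2).
#' @return List with `flags` (per-carrier logical), `flag_rate`,
#'   `expected_rate`, `branch` (`"logistic"` or `"threshold"`), and the
#'   group test (`or`, `p_value`).
#' @export
pgs_deviation_check <- function(carrier_scores, population_scores, k = 2) {
  if (length(carrier_scores) == 0) abort("empty carrier set.")
  mu <- mean(population_scores); s <- sd(population_scores)
  flags <- abs(carrier_scores - mu) > k * s
  expected <- 2 * pnorm(-k)
  if (length(carrier_scores) > 10) {
    y <- c(rep(1L, length(carrier_scores)), rep(0L, length(population_scores)))
    x <- c(carrier_scores, population_scores)
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    cf <- summary(fit)$coefficients
    group <- list(or = exp(cf["x", "Estimate"]), p_value = cf["x", "Pr(>|z|)"])
    branch <- "logistic"
  } else {
    bt <- binom.test(sum(flags), length(flags), p = expected)
    group <- list(or = NA_real_, p_value = bt$p.value)
    branch <- "threshold"
  }
  list(flags = flags, flag_rate = mean(flags), expected_rate = expected,
       branch = branch, group_or = group$or, group_p = group$p_value, k = k)
}
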