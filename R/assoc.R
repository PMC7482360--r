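# Single-variant association, summary-statistic QC and inverse-variance
# fixed-effects meta-analysis.

#' Harmonized variant identifier
#'
#' Builds the `chrom:pos_allele1_allele2` identifier used to match variants
#' across cohorts. Alleles are ordered lexicographically; alleles of unequal
#' length (indels) are ordered shorter-first, so the identifier is invariant
#' to which allele is listed first in a cohort file.
#'
#' @param chrom Chromosome label(s).
#' @param pos 1-based position(s).
#' @param allele1,allele2 Uppercase DNA allele strings (A/C/G/T, possibly
#'   multi-base for indels).
#' @return Character vector of harmonized IDs.
#' @export
harmonize_variant_id <- function(chrom, pos, allele1, allele2) {
  a1 <- as.character(allele1); a2 <- as.character(allele2)
  if (any(!grepl("^[ACGT]+$", a1)) || any(!grepl("^[ACGT]+$", a2))) {
    abort("alleles must be non-empty uppercase ACGT strings.")
  }
  n1 <- nchar(a1); n2 <- nchar(a2)
  swap <- (n1 > n2) | (n1 == n2 & a1 > a2)
  first <- ifelse(swap, a2, a1)
  second <- ifelse(swap, a1, a2)
  sprintf("%s:%d_%s_%s", as.character(chrom), as.integer(pos), first, second)
}

#' Filter summary statistics on imputation quality and allele count
#'
#' Removes variants whose INFO score is at or below `info_max_excluded` or
#' whose minor allele count `MAC = 2 * N * min(EAF, 1 - EAF)` is at or below
#' `mac_max_excluded`. The default MAC cutoff of 5 matches the meta-analysis
#' filter for ordinary cohorts; very large cohorts conventionally use the
#' stricter cutoff of 20 to exclude extremely rare variants with extreme
#' effects.
#'
#' @param stats Tibble of summary statistics with columns `eaf`, `info`,
#'   `n`.
#' @param info_max_excluded Variants with `info <=` this value are removed.
#' @param mac_max_excluded Variants with `MAC <=` this value are removed.
#' @return The filtered tibble; attribute `qc_removed` counts removals by
#'   reason.
#' @export
qc_filter <- function(stats, info_max_excluded = 0.4, mac_max_excluded = 5) {
  stats <- tibble::as_tibble(stats)
  need <- c("eaf", "info", "n")
  miss <- setdiff(need, names(stats))
  if (length(miss) > 0) {
    abort(sprintf("missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  mac <- 2 * stats$n * pmin(stats$eaf, 1 - stats$eaf)
  bad_info <- stats$info <= info_max_excluded
  bad_mac <- mac <= mac_max_excluded
  out <- stats[!(bad_info | bad_mac), , drop = FALSE]
  attr(out, "qc_removed") <- c(info = sum(bad_info), mac = sum(bad_mac & !bad_info))
  out
}

#' Check allele-frequency concordance against a reference panel
#'
#' Flags variants whose cohort effect-allele frequency deviates from the
#' reference panel frequency by more than `tolerance` — the usual symptom of
#' a strand or allele flip.
#'
#' @param cohort_eaf,reference_eaf Effect-allele frequencies in (0, 1),
#'   matched on harmonized ID and effect allele; equal length.
#' @param tolerance Maximum allowed absolute difference.
#' @return Tibble `cohort_eaf`, `reference_eaf`, `abs_diff`, `concordant`;
#'   attribute `n_discordant`.
#' @export
allele_freq_check <- function(cohort_eaf, reference_eaf, tolerance = 0.2) {
  if (length(cohort_eaf) != length(reference_eaf)) {
    abort("frequency vectors must have equal length (matched on harmonized ID).")
  }
  if (any(cohort_eaf <= 0 | cohort_eaf >= 1) || any(reference_eaf <= 0 | reference_eaf >= 1)) {
    abort("frequencies must be in (0, 1).")
  }
  d <- abs(cohort_eaf - reference_eaf)
  out <- tibble::tibble(cohort_eaf = cohort_eaf, reference_eaf = reference_eaf,
                        abs_diff = d, concordant = d <= tolerance)
  attr(out, "n_discordant") <- sum(!out$concordant)
  out
}

# Vectorized per-variant OLS of y on each dosage column.
# Returns beta, se, p (t distribution, df n-2) and flags monomorphic columns.
fast_marginal_scan <- function(X, y) {
  n <- nrow(X)
  xm <- colMeans(X)
  ym <- mean(y)
  sxx <- colSums(X^2) - n * xm^2
  mono <- sxx <= .Machine$double.eps * n
  sxy <- as.vector(crossprod(X, y)) - n * xm * ym
  syy <- sum(y^2) - n * ym^2
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  list(beta = beta, se = se, p = p, monomorphic = mono)
}

#' Genome-wide single-variant association scan
#'
#' Per-variant ordinary least squares of an adjusted, inverse-normalized
#' phenotype on allele dosage under the additive genetic model, with
#' two-sided p-values from the t distribution. On unrelated samples this is
#' the association model of the discovery stage. Monomorphic variants are
#' skipped and counted.
#'
#' @param G A [geno_matrix()].
#' @param y Adjusted phenotype residuals, aligned with the samples of `G`.
#' @return Tibble of summary statistics (`id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `info`, `beta`, `se`, `p`,
#'   `n`); attribute `n_monomorphic_skipped`.
#' @export
single_variant_scan <- function(G, y) {
  stopifnot(inherits(G, "geno_matrix"))
  X <- G$dosages
  if (length(y) != nrow(X)) abort("`y` must align with the samples of `G`.")
  sc <- fast_marginal_scan(X, y)
  keep <- !sc$monomorphic
  v <- G$variants
  out <- tibble::tibble(
    id = v$id[keep], chrom = v$chrom[keep], pos = v$pos[keep],
    effect_allele = v$alt[keep], other_allele = v$ref[keep],
    eaf = v$eaf[keep], info = v$info[keep],
    beta = sc$beta[keep], se = sc$se[keep], p = sc$p[keep],
    n = nrow(X)
  )
  n_skip <- sum(sc$monomorphic)
  if (n_skip > 0) inform(sprintf("skipped %d monomorphic variant(s).", n_skip))
  attr(out, "n_monomorphic_skipped") <- n_skip
  out
}

#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Pools per-cohort effect estimates for each variant with weights
#' `w_i = 1/SE_i^2`: pooled `beta = sum(w_i beta_i) / sum(w_i)`,
#' `SE = 1/sqrt(sum(w_i))`, `p = 2 * pnorm(-|beta/SE|)`, `N = sum(N_i)`.
#' Cohorts reporting the swapped allele pair for a variant are flipped
#' (beta sign and EAF) onto the first cohort's effect allele before pooling.
#'
#' @param stats Tibble of per-cohort summary statistics with columns `id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `n`, and
#'   optionally `cohort`.
#' @return Tibble with one pooled record per variant ID, including the
#'   number of contributing cohorts.
#' @export
meta_fixed_effects <- function(stats) {
  stats <- tibble::as_tibble(stats)
  need <- c("id", "effect_allele", "other_allele", "eaf", "beta", "se", "n")
  miss <- setdiff(need, names(stats))
  if (length(miss) > 0) {
    abort(sprintf("missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  if (nrow(stats) == 0) abort("no cohort records supplied.")
  if (any(stats$se <= 0)) abort("all standard errors must be > 0.")

  pool_one <- function(df) {
    ref_ea <- df$effect_allele[1]
    ref_oa <- df$other_allele[1]
    flip <- df$effect_allele == ref_oa & df$other_allele == ref_ea
    ok <- flip | (df$effect_allele == ref_ea & df$other_allele == ref_oa)
    if (!all(ok)) {
      abort(sprintf("allele mismatch for variant %s.", df$id[1]))
    }
    beta <- ifelse(flip, -df$beta, df$beta)
    eaf <- ifelse(flip, 1 - df$eaf, df$eaf)
    w <- 1 / df$se^2
    b <- sum(w * beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    tibble::tibble(
      id = df$id[1], effect_allele = ref_ea, other_allele = ref_oa,
      eaf = sum(df$n * eaf) / sum(df$n),
      beta = b, se = se, p = 2 * pnorm(-abs(b / se)),
      n = sum(df$n), n_cohorts = nrow(df)
    )
  }
  stats |>
    dplyr::group_by(.data$id) |>
    dplyr::group_split() |>
    purrr::map(pool_one) |>
    dplyr::bind_rows()
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  assert_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_count(n_tests, "n_tests")
  alpha / n_tests
}
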