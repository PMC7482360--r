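# Synthetic cohort generator: genotypes with haplotype-block LD, quantitative
# phenotypes with sparse + polygenic architecture, coexpression networks with
# designated core genes, trans-eQTL tables, and liability-driven disease labels.
# Every generator is seeded and bit-reproducible.

#' Simulation configuration for a synthetic genotype/phenotype cohort
#'
#' Bundles the parameters of the cohort generator: cohort and panel size,
#' haplotype-block structure, the minor-allele-frequency spectrum, the sparse
#' large-effect causal architecture, the dense polygenic background, and
#' covariate effects. The generator emulates the data structure of a large
#' population-biobank blood-trait GWAS: unrelated samples, blockwise linkage
#' disequilibrium, and phenotypes on an (approximately) unit-variance scale
#' after covariate adjustment.
#'
#' @param n_samples Number of individuals.
#' @param n_variants Number of variants.
#' @param ld_block_span Variants per haplotype block. Within a block adjacent
#'   variants are correlated by mosaic copying from a founder haplotype pool;
#'   across blocks variants are independent. `1` gives a fully independent
#'   panel.
#' @param maf_range Length-2 numeric in (0, 0.5]: per-variant allele
#'   frequencies are drawn uniformly from this interval.
#' @param causal_spec Data frame (or tibble) with columns `index` (1-based
#'   variant index) and `beta` (effect in phenotype SD per allele), or `NULL`
#'   for no sparse causal effects.
#' @param h2_polygenic Fraction of phenotype variance contributed by a dense
#'   polygenic background spread over all non-causal variants, in `[0, 1)`.
#' @param covariate_effects Named list of coefficients for `age`, `age2`,
#'   `sex` and `pc` (a vector, one coefficient per principal component).
#'   Defaults to no covariate effect.
#' @param n_pcs Number of simulated ancestry principal components.
#' @param mode `"hard"` for dosages in `{0, 1, 2}` or `"dosage"` for noisy
#'   imputed-style dosages in `[0, 2]` with a per-variant INFO score.
#' @param dosage_noise_sd Gaussian noise SD added to hard calls in dosage
#'   mode, before clamping to `[0, 2]`.
#' @param n_founders Founder haplotypes per block pool.
#' @param switch_rate Per-adjacent-variant probability that the mosaic copy
#'   switches founder haplotype; smaller values give longer-range LD.
#' @param founder_rho Lag-1 correlation of the latent Gaussian process that
#'   generates founder haplotypes; controls how strong within-block LD is.
#' @param chrom Chromosome label assigned to all variants.
#' @param pos_start,pos_step Base-pair position of the first variant and the
#'   spacing between consecutive variants.
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce bit-identical cohorts.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_variants, ld_block_span = 10L,
                       maf_range = c(0.05, 0.5), causal_spec = NULL,
                       h2_polygenic = 0, covariate_effects = list(),
                       n_pcs = 2L, mode = c("hard", "dosage"),
                       dosage_noise_sd = 0.15, n_founders = 20L,
                       switch_rate = 0.1, founder_rho = 0.95,
                       chrom = "1", pos_start = 1e6,
                       pos_step = 2000, seed = 1L) {
  assert_count(n_samples, "n_samples")
  assert_count(n_variants, "n_variants")
  assert_count(ld_block_span, "ld_block_span")
  assert_count(n_founders, "n_founders", min = 2L)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      any(maf_range <= 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair of fractions in (0, 0.5].")
  }
  assert_scalar_number(h2_polygenic, "h2_polygenic", 0, 1, strict_upper = TRUE)
  assert_scalar_number(switch_rate, "switch_rate", 0, 1)
  assert_scalar_number(founder_rho, "founder_rho", 0, 1, strict_upper = TRUE)
  mode <- match.arg(mode)
  if (!is.null(causal_spec)) {
    causal_spec <- tibble::as_tibble(causal_spec)
    if (!all(c("index", "beta") %in% names(causal_spec))) {
      abort("`causal_spec` needs columns `index` and `beta`.")
    }
    if (anyDuplicated(causal_spec$index) ||
        any(causal_spec$index < 1) || any(causal_spec$index > n_variants)) {
      abort("causal indices must be unique and within [1, n_variants].")
    }
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
      ld_block_span = as.integer(ld_block_span), maf_range = maf_range,
      causal_spec = causal_spec, h2_polygenic = h2_polygenic,
      covariate_effects = covariate_effects, n_pcs = as.integer(n_pcs),
      mode = mode, dosage_noise_sd = dosage_noise_sd,
      n_founders = as.integer(n_founders), switch_rate = switch_rate,
      founder_rho = founder_rho,
      chrom = as.character(chrom), pos_start = pos_start, pos_step = pos_step,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Genotype container
#'
#' Holds a samples-by-variants dosage matrix alongside per-variant metadata
#' and per-sample covariates.
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns;
#'   column names are harmonized variant IDs.
#' @param variants Tibble of per-variant metadata (`id`, `chrom`, `pos`,
#'   `ref`, `alt`, `eaf`, `info`); `alt` is the counted (effect) allele.
#' @param samples Tibble of per-sample covariates, first column `sample_id`.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants, samples) {
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix.")
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  if (nrow(variants) != ncol(dosages)) abort("variant metadata does not match dosage columns.")
  if (nrow(samples) != nrow(dosages)) abort("sample table does not match dosage rows.")
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  print(head(x$variants, 5))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

# Accept either a geno_matrix or a bare dosage matrix.
as_dosage_matrix <- function(G) {
  if (inherits(G, "geno_matrix")) G$dosages else as.matrix(G)
}

# One haplotype block: founder pool of `n_founders` haplotypes generated
# from an AR(1) Gaussian copula (lag-1 latent correlation `founder_rho`),
# thresholded at the per-variant allele frequency so founders carry
# decaying LD at the target marginal frequencies; 2*n sample haplotypes are
# then assembled by mosaic copying with per-step switch probability
# `switch_rate`.
sim_block <- function(n_samples, m, maf_lo, maf_hi, n_founders, switch_rate,
                      founder_rho = 0.95) {
  p <- runif(m, maf_lo, maf_hi)
  Z <- matrix(0, nrow = n_founders, ncol = m)
  Z[, 1L] <- rnorm(n_founders)
  if (m > 1L) {
    for (v in 2:m) {
      Z[, v] <- founder_rho * Z[, v - 1L] +
        sqrt(1 - founder_rho^2) * rnorm(n_founders)
    }
  }
  founders <- matrix(0L, nrow = n_founders, ncol = m)
  founders[Z < matrix(qnorm(p), n_founders, m, byrow = TRUE)] <- 1L
  nh <- 2L * n_samples
  # switch indicator; position 1 always draws a founder
  sw <- matrix(runif(nh * m) < switch_rate, nrow = nh, ncol = m)
  sw[, 1L] <- TRUE
  draws <- matrix(sample.int(n_founders, nh * m, replace = TRUE),
                  nrow = nh, ncol = m)
  # carry the current founder forward between switches, column by column
  fid <- matrix(0L, nrow = nh, ncol = m)
  cur <- draws[, 1L]
  fid[, 1L] <- cur
  if (m > 1L) {
    for (v in 2:m) {
      sel <- sw[, v]
      cur[sel] <- draws[sel, v]
      fid[, v] <- cur
    }
  }
  hap <- matrix(founders[cbind(as.vector(fid), rep(seq_len(m), each = nh))],
                nrow = nh, ncol = m)
  hap[seq_len(n_samples), , drop = FALSE] +
    hap[n_samples + seq_len(n_samples), , drop = FALSE]
}

#' Simulate genotype dosages with haplotype-block LD
#'
#' Generates hard-call or noisy ("imputed") dosages for a panel of variants
#' organised in haplotype blocks. Within a block, sample haplotypes are
#' mosaics of a small founder pool, which induces the decaying pairwise
#' r-squared structure of real imputed panels; variants in different blocks
#' are independent. In dosage mode, Gaussian noise is added to the hard calls
#' and each variant's INFO score is recorded as the ratio of the
#' Hardy-Weinberg expected dosage variance to the observed dosage variance,
#' capped at 1 — so low-quality variants have something real for the QC
#' filter to act on.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] with per-variant `eaf` and `info` populated.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    m <- config$n_variants
    blocks <- split(seq_len(m), ceiling(seq_len(m) / config$ld_block_span))
    dos <- matrix(0, nrow = n, ncol = m)
    for (idx in blocks) {
      dos[, idx] <- sim_block(n, length(idx), config$maf_range[1],
                              config$maf_range[2], config$n_founders,
                              config$switch_rate, config$founder_rho)
    }
    eaf <- colMeans(dos) / 2
    info <- rep(1, m)
    if (config$mode == "dosage") {
      noisy <- dos + matrix(rnorm(n * m, sd = config$dosage_noise_sd),
                            nrow = n, ncol = m)
      noisy <- pmin(pmax(noisy, 0), 2)
      vobs <- apply(noisy, 2L, var)
      vexp <- 2 * eaf * (1 - eaf)
      info <- ifelse(vobs > 0, pmin(vexp / vobs, 1), 0)
      dos <- noisy
    }
    pos <- as.integer(round(config$pos_start + (seq_len(m) - 1L) * config$pos_step))
    ref <- rep("A", m)
    alt <- rep("G", m)
    variants <- tibble::tibble(
      id = harmonize_variant_id(config$chrom, pos, ref, alt),
      chrom = config$chrom, pos = pos, ref = ref, alt = alt,
      eaf = eaf, info = info
    )
    cov <- config$covariate_effects
    n_pcs <- config$n_pcs
    samples <- tibble::tibble(
      sample_id = sprintf("S%06d", seq_len(n)),
      age = runif(n, 40, 70),
      sex = rbinom(n, 1L, 0.5)
    )
    if (n_pcs > 0L) {
      pcs <- matrix(rnorm(n * n_pcs), nrow = n,
                    dimnames = list(NULL, paste0("pc", seq_len(n_pcs))))
      samples <- dplyr::bind_cols(samples, tibble::as_tibble(pcs))
    }
    geno_matrix(dos, variants, samples)
  })
}

#' Simulate a quantitative phenotype on a genotype matrix
#'
#' The phenotype is the sum of (i) the sparse large-effect causal variants in
#' `config$causal_spec` acting additively on centered dosages, (ii) a dense
#' polygenic background with variance `h2_polygenic` spread over all
#' non-causal variants, (iii) covariate effects (age, age squared, sex,
#' principal components), and (iv) Gaussian noise scaled so the total
#' variance is approximately 1. The realized effect of every variant is
#' stored in the `truth` attribute for recovery tests.
#'
#' @param G A [geno_matrix()] from [simulate_genotypes()].
#' @param config The same [sim_config()] (its `seed` is offset internally so
#'   genotypes and phenotype noise are independent streams).
#' @return A tibble with `sample_id`, `phenotype` and the covariate columns;
#'   attribute `truth` holds a list with the causal table, the per-variant
#'   polygenic weights, and the realized variance components.
#' @export
simulate_phenotype <- function(G, config) {
  stopifnot(inherits(G, "geno_matrix"), inherits(config, "sim_config"))
  X <- G$dosages
  n <- nrow(X); m <- ncol(X)
  causal <- config$causal_spec
  if (!is.null(causal) && nrow(causal) > 0 && max(causal$index) > m) {
    abort("causal indices exceed the number of variants in `G`.")
  }
  with_seed(config$seed + 1L, {
    sparse <- numeric(n)
    if (!is.null(causal) && nrow(causal) > 0) {
      Xc <- scale(X[, causal$index, drop = FALSE], center = TRUE, scale = FALSE)
      sparse <- as.vector(Xc %*% causal$beta)
    }
    var_sparse <- if (all(sparse == 0)) 0 else var(sparse)

    poly <- numeric(n)
    poly_w <- NULL
    if (config$h2_polygenic > 0) {
      bg_idx <- setdiff(seq_len(m), causal$index %||% integer())
      if (length(bg_idx) == 0L) abort("no background variants left for the polygenic term.")
      Xb <- X[, bg_idx, drop = FALSE]
      sds <- apply(Xb, 2L, sd)
      keep <- sds > 0
      Xb <- scale(Xb[, keep, drop = FALSE])
      w <- rnorm(ncol(Xb))
      raw <- as.vector(Xb %*% w)
      poly <- raw / sd(raw) * sqrt(config$h2_polygenic)
      poly_w <- tibble::tibble(index = bg_idx[keep], weight = w / sd(raw) * sqrt(config$h2_polygenic))
    }

    covs <- numeric(n)
    ce <- config$covariate_effects
    if (length(ce) > 0) {
      s <- G$samples
      if (!is.null(ce$age)) covs <- covs + ce$age * (s$age - mean(s$age))
      if (!is.null(ce$age2)) covs <- covs + ce$age2 * (s$age^2 - mean(s$age^2))
      if (!is.null(ce$sex)) covs <- covs + ce$sex * (s$sex - mean(s$sex))
      if (!is.null(ce$pc)) {
        for (j in seq_along(ce$pc)) {
          covs <- covs + ce$pc[j] * s[[paste0("pc", j)]]
        }
      }
    }
    var_cov <- if (all(covs == 0)) 0 else var(covs)

    var_noise <- 1 - var_sparse - config$h2_polygenic - var_cov
    if (var_noise <= 0) {
      abort(sprintf(
        "variance budget exceeded: sparse %.3f + polygenic %.3f + covariates %.3f >= 1",
        var_sparse, config$h2_polygenic, var_cov
      ))
    }
    y <- sparse + poly + covs + rnorm(n, sd = sqrt(var_noise))

    out <- dplyr::bind_cols(
      tibble::tibble(sample_id = G$samples$sample_id, phenotype = y),
      G$samples[setdiff(names(G$samples), "sample_id")]
    )
    attr(out, "truth") <- list(
      causal = causal, polygenic_weights = poly_w,
      var_sparse = var_sparse, h2_polygenic = config$h2_polygenic,
      var_covariates = var_cov, var_noise = var_noise,
      polygenic_component = poly
    )
    out
  })
}

#' Configuration for a synthetic gene coexpression network
#'
#' @param n_genes Number of genes.
#' @param n_core Number of designated core (Mendelian-like) genes.
#' @param base_degree Expected number of coexpression partners of a
#'   non-core gene at a moderate correlation cutoff.
#' @param core_degree_multiplier Fold increase of a core gene's expected
#'   degree relative to `base_degree`; `1` is the null configuration.
#' @param core_mutual_correlation Mean pairwise correlation among core
#'   genes, in `[0, 1)`. `0` reduces core-core pairs to the background
#'   level.
#' @param edge_strength Length-2 range from which the correlation of a
#'   non-core edge is drawn.
#' @param background_sd SD of the near-zero background correlations.
#' @param seed Integer seed.
#' @return An object of class `network_sim_config`.
#' @export
network_sim_config <- function(n_genes, n_core, base_degree = 5,
                               core_degree_multiplier = 1,
                               core_mutual_correlation = 0,
                               edge_strength = c(0.25, 0.5),
                               background_sd = 0.03, seed = 1L) {
  assert_count(n_genes, "n_genes", min = 2L)
  assert_count(n_core, "n_core", min = 0L)
  if (n_core > n_genes) abort("`n_core` must not exceed `n_genes`.")
  assert_scalar_number(base_degree, "base_degree", 0, Inf, strict_lower = TRUE)
  assert_scalar_number(core_degree_multiplier, "core_degree_multiplier", 0, Inf,
                       strict_lower = TRUE)
  assert_scalar_number(core_mutual_correlation, "core_mutual_correlation", 0, 1,
                       strict_upper = TRUE)
  structure(
    list(n_genes = as.integer(n_genes), n_core = as.integer(n_core),
         base_degree = base_degree,
         core_degree_multiplier = core_degree_multiplier,
         core_mutual_correlation = core_mutual_correlation,
         edge_strength = edge_strength, background_sd = background_sd,
         seed = as.integer(seed)),
    class = "network_sim_config"
  )
}

#' Gene network container
#'
#' @param correlation Symmetric gene-by-gene correlation matrix with unit
#'   diagonal, dimnames = gene names.
#' @param flags Tibble with columns `gene`, `core` (logical) and optionally
#'   `gwas` (logical).
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(correlation, flags) {
  flags <- tibble::as_tibble(flags)
  if (!isSymmetric(unname(correlation), tol = 1e-8)) abort("correlation matrix must be symmetric.")
  if (any(abs(diag(correlation) - 1) > 1e-8)) abort("correlation matrix must have unit diagonal.")
  if (nrow(flags) != nrow(correlation)) abort("flags do not match matrix dimension.")
  rownames(correlation) <- colnames(correlation) <- flags$gene
  structure(list(correlation = correlation, flags = flags), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d genes (%d core)\n",
              nrow(x$flags), sum(x$flags$core)))
  invisible(x)
}

#' Per-gene degree at a correlation cutoff
#'
#' A gene pair is linked when the absolute coexpression correlation exceeds
#' the cutoff; the degree of a gene is its number of links. Degrees are
#' non-increasing in the cutoff.
#'
#' @param network A [gene_network()].
#' @param cutoff Correlation cutoff in (0, 1).
#' @return Tibble `gene`, `core`, `degree`.
#' @export
network_degrees <- function(network, cutoff) {
  stopifnot(inherits(network, "gene_network"))
  assert_scalar_number(cutoff, "cutoff", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  A <- abs(network$correlation) > cutoff
  diag(A) <- FALSE
  tibble::tibble(gene = network$flags$gene, core = network$flags$core,
                 degree = as.integer(rowSums(A)))
}

#' Simulate a gene coexpression network with core genes
#'
#' Builds a correlation matrix in which (i) background gene pairs have
#' near-zero correlation, (ii) each gene participates in a sparse set of
#' coexpression edges with correlations drawn from `edge_strength`, with core
#' genes receiving `core_degree_multiplier` times more edges, and (iii) all
#' core-core pairs are drawn around `core_mutual_correlation`. The assembled
#' matrix is repaired to the nearest positive semi-definite correlation
#' matrix (Higham projection via [Matrix::nearPD()]) when needed.
#'
#' @param config A [network_sim_config()].
#' @return A [gene_network()].
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "network_sim_config"))
  with_seed(config$seed, {
    g <- config$n_genes
    core <- c(rep(TRUE, config$n_core), rep(FALSE, g - config$n_core))
    R <- matrix(rnorm(g * g, sd = config$background_sd), g, g)
    R <- (R + t(R)) / 2

    p0 <- min(config$base_degree / (g - 1), 1)
    p_core <- min(p0 * config$core_degree_multiplier, 0.95)
    up <- which(upper.tri(R), arr.ind = TRUE)
    pair_core <- core[up[, 1]] | core[up[, 2]]
    both_core <- core[up[, 1]] & core[up[, 2]]
    pe <- ifelse(both_core, 0, ifelse(pair_core, p_core, p0))
    is_edge <- runif(nrow(up)) < pe
    R[up[is_edge, , drop = FALSE]] <-
      runif(sum(is_edge), config$edge_strength[1], config$edge_strength[2])
    if (config$core_mutual_correlation > 0 && any(both_core)) {
      R[up[both_core, , drop = FALSE]] <-
        pmin(pmax(rnorm(sum(both_core), config$core_mutual_correlation, 0.05), -0.9), 0.9)
    }
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    diag(R) <- 1

    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
      rep <- Matrix::nearPD(R, corr = TRUE, keepDiag = TRUE,
                            posd.tol = 1e-6, maxit = 200)
      if (!rep$converged) abort("nearest-PSD repair of the correlation matrix failed.")
      R <- as.matrix(rep$mat)
      R <- stats::cov2cor(R)
    }
    genes <- sprintf("G%04d", seq_len(g))
    gene_network(R, tibble::tibble(gene = genes, core = core))
  })
}

#' Simulate a trans-eQTL table over a gene network
#'
#' Allocates `n_eqtls` trans-eQTL records to target genes with core genes
#' receiving `enrichment`-fold the expected count of non-core genes.
#' Absolute eQTL Z-scores and per-gene median expression levels are drawn
#' from the same distribution for core and non-core genes, so the matched
#' comparison downstream is confounder-free by construction.
#'
#' @param network A [gene_network()].
#' @param enrichment Fold enrichment of expected trans-eQTL counts for core
#'   genes; `1` is the null.
#' @param n_eqtls Total number of trans-eQTL records.
#' @param seed Integer seed.
#' @return A list with `eqtls` (tibble: `variant`, `gene`, `z`) and
#'   `expression` (tibble: `gene`, `median_expr`).
#' @export
simulate_trans_eqtls <- function(network, enrichment, n_eqtls, seed = 1L) {
  stopifnot(inherits(network, "gene_network"))
  if (enrichment < 0) abort("`enrichment` must be >= 0.")
  assert_count(n_eqtls, "n_eqtls")
  with_seed(seed, {
    flags <- network$flags
    w <- ifelse(flags$core, enrichment, 1)
    if (sum(w) == 0) abort("all target weights are zero.")
    counts <- as.vector(rmultinom(1L, n_eqtls, prob = w / sum(w)))
    gene <- rep(flags$gene, counts)
    eqtls <- tibble::tibble(
      variant = sprintf("rsSIM%06d", seq_len(n_eqtls)),
      gene = gene,
      z = sample(c(-1, 1), n_eqtls, replace = TRUE) * (4 + abs(rnorm(n_eqtls, 2, 1.5)))
    )
    expression <- tibble::tibble(
      gene = flags$gene,
      median_expr = rlnorm(nrow(flags), meanlog = 3, sdlog = 1)
    )
    list(eqtls = eqtls, expression = expression)
  })
}

#' Simulate binary disease status from a polygenic score
#'
#' Draws case/control labels from a logistic model
#' `logit P(case) = alpha + log(or_per_sd) * PGS`, with the intercept
#' calibrated numerically so the expected prevalence matches the target.
#'
#' @param pgs Standardized polygenic score vector.
#' @param or_per_sd Odds ratio per SD of the score; `1` is the null.
#' @param prevalence Target case fraction in (0, 1).
#' @param seed Integer seed.
#' @return Integer 0/1 label vector with attributes `or_per_sd` and
#'   `intercept`.
#' @export
simulate_disease <- function(pgs, or_per_sd, prevalence, seed = 1L) {
  if (or_per_sd <= 0) abort("`or_per_sd` must be > 0.")
  assert_scalar_number(prevalence, "prevalence", 0, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  b <- log(or_per_sd)
  alpha <- uniroot(function(a) mean(plogis(a + b * pgs)) - prevalence,
                   lower = -50, upper = 50, tol = 1e-10)$root
  with_seed(seed, {
    y <- rbinom(length(pgs), 1L, plogis(alpha + b * pgs))
    attr(y, "or_per_sd") <- or_per_sd
    attr(y, "intercept") <- alpha
    y
  })
}
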