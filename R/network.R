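# Omnigenic-model test battery on gene coexpression networks: permutation
# overlap enrichment, degree and core-coexpression tests, greedy covariate
# matching, MAF-matched effect-size comparison, trans-eQTL target enrichment
# and neighbor enrichment.

new_enrichment_result <- function(observed, null, n_perm, seed) {
  null_mean <- mean(null)
  structure(
    list(
      observed = observed, null_mean = null_mean,
      fold_enrichment = if (null_mean > 0) observed / null_mean else NA_real_,
      p_value = (1 + sum(null >= observed)) / (n_perm + 1),
      n_perm = n_perm, seed = seed, null = null
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> observed %.4g, null mean %.4g, FE = %.3f, p = %.3g (%d permutations)\n",
    x$observed, x$null_mean, x$fold_enrichment, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' Permutation overlap enrichment of a gene set
#'
#' Compares the observed overlap between a query gene set and an annotated
#' gene set against overlaps of random same-size gene draws from the
#' universe. Fold enrichment is observed over null mean; the permutation
#' p-value uses the add-one estimator `(1 + #{null >= observed}) /
#' (n_perm + 1)`, so it is floored at `1/(n_perm + 1)` and never zero.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param annotated Character vector of annotated genes (subset of
#'   `universe`).
#' @param universe Character vector of all eligible genes.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return An `enrichment_result`.
#' @export
overlap_enrichment <- function(query, annotated, universe, n_perm = 10000L,
                               seed = 1L) {
  if (length(universe) == 0 || length(query) == 0) {
    abort("`universe` and `query` must be non-empty.")
  }
  if (!all(query %in% universe) || !all(annotated %in% universe)) {
    abort("`query` and `annotated` must be subsets of `universe`.")
  }
  observed <- sum(query %in% annotated)
  in_ann <- universe %in% annotated
  k <- length(query)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(in_ann[sample.int(length(universe), k)]),
           double(1))
  })
  new_enrichment_result(observed, null, n_perm, seed)
}

#' Compare coexpression degrees of core and non-core genes
#'
#' Computes each gene's number of coexpression links at the given cutoff
#' and tests whether core genes have more links than the remaining genes by
#' a one-sided Wilcoxon rank-sum test.
#'
#' @param network A [gene_network()].
#' @param core_genes Character vector of core gene names present in the
#'   network.
#' @param cutoff Correlation cutoff in (0, 1).
#' @return Tibble with one row: `cutoff`, `median_core`, `median_other`,
#'   `p_value`, `degenerate`; attribute `degrees` holds the per-gene
#'   degrees.
#' @export
degree_test <- function(network, core_genes, cutoff) {
  stopifnot(inherits(network, "gene_network"))
  genes <- network$flags$gene
  if (!any(core_genes %in% genes)) abort("no core genes found in the network.")
  deg <- network_degrees(network, cutoff)
  deg$core <- deg$gene %in% core_genes
  core_d <- deg$degree[deg$core]
  other_d <- deg$degree[!deg$core]
  degenerate <- all(deg$degree == 0)
  p <- if (degenerate) {
    warn("all degrees are zero at this cutoff; p set to 1.")
    1
  } else {
    suppressWarnings(wilcox.test(core_d, other_d, alternative = "greater")$p.value)
  }
  out <- tibble::tibble(
    cutoff = cutoff, median_core = median(core_d),
    median_other = median(other_d), p_value = p, degenerate = degenerate
  )
  attr(out, "degrees") <- deg
  out
}

#' Mutual coexpression of core genes versus random gene sets
#'
#' The observed statistic is the median absolute coexpression coefficient
#' over all core-core gene pairs; the null distribution is that statistic
#' for equal-sized random gene draws.
#'
#' @param network A [gene_network()].
#' @param core_genes Character vector (>= 2 genes present in the network).
#' @param n_perm Number of random draws.
#' @param seed Integer seed.
#' @return An `enrichment_result` where `observed` and `null` are median
#'   absolute correlations.
#' @export
core_coexpression_test <- function(network, core_genes, n_perm = 10000L,
                                   seed = 1L) {
  stopifnot(inherits(network, "gene_network"))
  genes <- network$flags$gene
  core_idx <- which(genes %in% core_genes)
  if (length(core_idx) < 2) abort("need at least 2 core genes in the network.")
  R <- abs(network$correlation)
  med_offdiag <- function(idx) {
    sub <- R[idx, idx]
    median(sub[upper.tri(sub)])
  }
  observed <- med_offdiag(core_idx)
  k <- length(core_idx)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) med_offdiag(sample.int(length(genes), k)),
           double(1))
  })
  new_enrichment_result(observed, null, n_perm, seed)
}

#' Greedy nearest-neighbor covariate matching
#'
#' Matches each treated item to `ratio` control items without replacement,
#' minimising covariate distance (Euclidean after rank-scaling each
#' covariate). Matching is deterministic: treated items are processed in
#' order of their first covariate, and distance ties resolve to the lowest
#' index.
#'
#' @param values Numeric vector, matrix or data frame of matching
#'   covariates (rows = items).
#' @param treated Logical vector flagging treated items.
#' @param ratio Controls matched per treated item.
#' @return Tibble `treated_index`, `control_index`, `distance`.
#' @export
match_nearest <- function(values, treated, ratio = 1L) {
  v <- as.matrix(values)
  if (!is.logical(treated) || length(treated) != nrow(v)) {
    abort("`treated` must be a logical vector matching `values`.")
  }
  ratio <- assert_count(ratio, "ratio")
  t_idx <- which(treated)
  c_idx <- which(!treated)
  if (length(c_idx) < ratio * length(t_idx)) {
    abort(sprintf("insufficient controls: need %d, have %d.",
                  ratio * length(t_idx), length(c_idx)))
  }
  vs <- rank_scale(v)
  t_ord <- t_idx[order(vs[t_idx, 1L])]
  available <- rep(TRUE, length(c_idx))
  out <- vector("list", ratio * length(t_ord))
  k <- 0L
  for (r in seq_len(ratio)) {
    for (ti in t_ord) {
      d <- sqrt(colSums((t(vs[c_idx, , drop = FALSE]) - vs[ti, ])^2))
      d[!available] <- Inf
      j <- which.min(d)
      available[j] <- FALSE
      k <- k + 1L
      out[[k]] <- tibble::tibble(treated_index = ti, control_index = c_idx[j],
                                 distance = d[j])
    }
  }
  dplyr::bind_rows(out)
}

#' MAF-matched effect-size comparison of core-gene variants
#'
#' Within each functional annotation class, control variants are matched to
#' core-gene variants on minor allele frequency; the fold change is the
#' ratio of median absolute effect sizes (core over matched controls), with
#' a Wilcoxon rank-sum p-value. Classes with fewer than `min_per_group`
#' variants in either group are skipped and logged.
#'
#' @param variants Tibble with columns `abs_beta`, `maf`, `class`
#'   (annotation class) and `core` (logical).
#' @param min_per_group Minimum variants per group per class (default 10).
#' @return Tibble per retained class: `class`, `n_core`, `n_matched`,
#'   `fold_change`, `p_value`; attribute `skipped_classes`.
#' @export
matched_effect_comparison <- function(variants, min_per_group = 10L) {
  variants <- tibble::as_tibble(variants)
  need <- c("abs_beta", "maf", "class", "core")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) abort(sprintf("missing column(s): %s.", paste(miss, collapse = ", ")))
  skipped <- character(0)
  rows <- list()
  for (cl in unique(variants$class)) {
    d <- variants[variants$class == cl, , drop = FALSE]
    n_core <- sum(d$core); n_ctrl <- sum(!d$core)
    if (n_core < min_per_group || n_ctrl < min_per_group) {
      skipped <- c(skipped, cl)
      inform(sprintf("class `%s` skipped: %d core / %d control variants (need >= %d).",
                     cl, n_core, n_ctrl, min_per_group))
      next
    }
    mt <- match_nearest(d$maf, d$core, ratio = 1L)
    core_b <- d$abs_beta[mt$treated_index]
    ctrl_b <- d$abs_beta[mt$control_index]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      class = cl, n_core = n_core, n_matched = length(ctrl_b),
      fold_change = median(core_b) / median(ctrl_b),
      p_value = suppressWarnings(
        wilcox.test(core_b, ctrl_b, alternative = "greater")$p.value
      )
    )
  }
  if (length(rows) == 0) abort("no annotation class has enough variants in both groups.")
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped_classes") <- skipped
  out
}

#' Trans-eQTL target enrichment of core genes with matching
#'
#' Compares the number of trans-eQTLs per gene between core genes and
#' non-core genes matched on rank-inverse-normalized median expression and
#' mean absolute eQTL z-score (to account for detection-power differences).
#' The fold estimate is the ratio of mean per-gene counts (core over
#' matched); the p-value is a one-sided Wilcoxon rank-sum test.
#'
#' @param eqtls Tibble with columns `gene` and `z` (one row per trans-eQTL
#'   record).
#' @param core_genes Character vector of core gene names.
#' @param expression Tibble with columns `gene` and `median_expr`.
#' @return Tibble with one row: `n_core`, `n_matched`, `fold`, `p_value`;
#'   attribute `per_gene` holds the per-gene counts.
#' @export
trans_eqtl_enrichment <- function(eqtls, core_genes, expression) {
  eqtls <- tibble::as_tibble(eqtls)
  expression <- tibble::as_tibble(expression)
  if (!all(c("gene", "z") %in% names(eqtls))) abort("`eqtls` needs columns `gene`, `z`.")
  if (!all(c("gene", "median_expr") %in% names(expression))) {
    abort("`expression` needs columns `gene`, `median_expr`.")
  }
  per_gene <- eqtls |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_eqtls = dplyr::n(), mean_abs_z = mean(abs(.data$z)),
                     .groups = "drop")
  if (nrow(per_gene) < 4) {
    abort("trans-eQTL table is degenerate: fewer than 4 distinct target genes.")
  }
  d <- dplyr::inner_join(per_gene, expression, by = "gene")
  d$core <- d$gene %in% core_genes
  if (sum(d$core) < 2 || sum(!d$core) < 2) {
    abort("need at least 2 core and 2 non-core target genes with expression.")
  }
  d$expr_int <- inverse_normal_transform(d$median_expr)
  mt <- match_nearest(cbind(d$expr_int, d$mean_abs_z), d$core, ratio = 1L)
  core_counts <- d$n_eqtls[mt$treated_index]
  ctrl_counts <- d$n_eqtls[mt$control_index]
  out <- tibble::tibble(
    n_core = length(core_counts), n_matched = length(ctrl_counts),
    fold = mean(core_counts) / mean(ctrl_counts),
    p_value = suppressWarnings(
      wilcox.test(core_counts, ctrl_counts, alternative = "greater")$p.value
    )
  )
  attr(out, "per_gene") <- d
  out
}

#' Enrichment of a gene set among network neighbors of core genes
#'
#' Builds the set of genes within graph distance `degree` (1 or 2) of any
#' core gene at the given correlation cutoff, then tests whether the query
#' set overlaps that neighbor set more than random same-size query draws.
#'
#' @param network A [gene_network()].
#' @param core_genes Character vector of core genes.
#' @param query Character vector of query genes (e.g. GWAS-annotated
#'   genes).
#' @param degree Neighborhood order, 1 or 2.
#' @param cutoff Correlation cutoff in (0, 1).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return An `enrichment_result`; attribute `neighbors` lists the
#'   neighbor-set genes.
#' @export
neighbor_enrichment <- function(network, core_genes, query, degree = 1L,
                                cutoff, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(network, "gene_network"))
  if (!degree %in% c(1L, 2L)) abort("`degree` must be 1 or 2.")
  genes <- network$flags$gene
  A <- abs(network$correlation) > cutoff
  diag(A) <- FALSE
  core_idx <- which(genes %in% core_genes)
  if (length(core_idx) == 0) abort("no core genes found in the network.")
  n1 <- which(rowSums(A[, core_idx, drop = FALSE]) > 0)
  nb <- n1
  if (degree == 2L && length(n1) > 0) {
    n2 <- which(rowSums(A[, n1, drop = FALSE]) > 0)
    nb <- union(n1, n2)
  }
  if (length(nb) == 0) abort("the neighbor set is empty at this cutoff.")
  neighbors <- genes[nb]
  res <- overlap_enrichment(query = query, annotated = neighbors,
                            universe = genes, n_perm = n_perm, seed = seed)
  attr(res, "neighbors") <- neighbors
  res
}
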