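# Bayesian fine-mapping by exhaustive enumeration of causal configurations:
# region definition around sentinels, configuration Bayes factors under the
# summary-statistic multivariate normal model, posterior inclusion
# probabilities and minimal 95% credible sets.

#' Define fine-mapping regions around sentinel variants
#'
#' Each sentinel contributes a window of `flank` bp either side of its
#' position; transitively overlapping windows on the same chromosome are
#' merged. The maximum number of causal variants searched in a region (`k`)
#' equals the number of sentinels it contains, which encodes the number of
#' conditionally independent signals as prior knowledge.
#'
#' @param sentinels Tibble with columns `id`, `chrom`, `pos`, sorted by
#'   position within chromosome.
#' @param flank Half-window in bp (default 250 kb, giving 500 kb windows
#'   before merging).
#' @return Tibble `region`, `chrom`, `start`, `end`, `k`, `sentinel_ids`
#'   (list column).
#' @export
define_regions <- function(sentinels, flank = 250000) {
  sentinels <- tibble::as_tibble(sentinels)
  if (!all(c("id", "chrom", "pos") %in% names(sentinels))) {
    abort("`sentinels` needs columns `id`, `chrom`, `pos`.")
  }
  out <- list()
  for (ch in unique(sentinels$chrom)) {
    s <- sentinels[sentinels$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    start <- s$pos[1] - flank; end <- s$pos[1] + flank
    members <- s$id[1]
    flush <- function(start, end, members) {
      tibble::tibble(
        region = sprintf("%s:%d-%d", ch, start, end), chrom = ch,
        start = start, end = end, k = length(members),
        sentinel_ids = list(members)
      )
    }
    if (nrow(s) > 1) {
      for (i in 2:nrow(s)) {
        ws <- s$pos[i] - flank; we <- s$pos[i] + flank
        if (ws <= end) {
          end <- max(end, we)
          members <- c(members, s$id[i])
        } else {
          out[[length(out) + 1L]] <- flush(start, end, members)
          start <- ws; end <- we; members <- s$id[i]
        }
      }
    }
    out[[length(out) + 1L]] <- flush(start, end, members)
  }
  dplyr::bind_rows(out)
}

#' Log Bayes factor of a causal configuration
#'
#' Under the summary-statistic Bayesian linear model with Gaussian effect
#' prior of standard deviation `s` (0.08 by default), the z-scores of a
#' configuration `gamma` are marginally
#' `N(0, R_gg + n s^2 R_gg R_gg)` under the causal model and `N(0, R_gg)`
#' under the null, where `R_gg` is the LD submatrix. For a single variant
#' this reduces to the Wakefield approximate Bayes factor.
#'
#' @param z Vector of per-variant z-scores for the region.
#' @param R LD (correlation) matrix of the region, unit diagonal.
#' @param config Integer indices of the variants in the configuration.
#' @param s Prior effect-size standard deviation.
#' @param n GWAS sample size.
#' @return Log Bayes factor; `NA` when the configuration's LD submatrix is
#'   singular (perfectly correlated variants), which callers skip.
#' @export
config_log_bf <- function(z, R, config, s = 0.08, n) {
  if (length(config) == 0) abort("`config` must be a non-empty variant subset.")
  zg <- z[config]
  Rg <- R[config, config, drop = FALSE]
  l0 <- ldmvnorm0(zg, Rg)
  l1 <- ldmvnorm0(zg, Rg + n * s^2 * (Rg %*% Rg))
  if (is.na(l0) || is.na(l1)) return(NA_real_)
  l1 - l0
}

#' Enumerate causal-configuration posteriors for a region
#'
#' Computes the posterior over all causal configurations of size 1..K by
#' exhaustive enumeration: `posterior(gamma)` is proportional to
#' `prior(gamma) * BF(gamma)`, with a prior uniform over the number of
#' causal variants k and uniform over configurations within each k.
#' Per-variant posterior inclusion probabilities (PIP) are the summed
#' posteriors of configurations containing the variant, and the 95%
#' credible set is derived by the PIP-greedy rule (see [credible_set()]).
#'
#' @param z Per-variant z-scores.
#' @param R LD matrix (unit diagonal, positive semi-definite).
#' @param K Maximum number of causal variants (typically the number of
#'   conditionally independent signals in the region).
#' @param s Prior effect-size SD (default 0.08).
#' @param n GWAS sample size.
#' @param level Credible-set coverage level.
#' @param variant_ids Optional variant names; defaults to `names(z)` or
#'   indices.
#' @param max_configs Enumeration guard: error if the number of
#'   configurations exceeds this bound (reduce the region or K).
#' @return A `finemap_result`: list with `configs` (tibble: `config` list
#'   column, `k`, `log_bf`, `posterior`), `pip` (tibble: `variant`, `pip`,
#'   `in_credible_set`), `credible_set`, `level`, `coverage`, `k_max`, `s`,
#'   `n`.
#' @export
enumerate_posteriors <- function(z, R, K, s = 0.08, n, level = 0.95,
                                 variant_ids = NULL, max_configs = 2e6) {
  m <- length(z)
  K <- assert_count(K, "K")
  if (K > m) K <- m
  n_conf <- sum(choose(m, seq_len(K)))
  if (n_conf > max_configs) {
    abort(sprintf(
      "%.3g configurations exceed the enumeration guard (%.3g); reduce the region or K.",
      n_conf, max_configs
    ))
  }
  ids <- variant_ids %||% names(z) %||% as.character(seq_len(m))

  configs <- list(); ks <- integer(0); log_prior <- double(0)
  for (k in seq_len(K)) {
    cs <- combn(m, k, simplify = FALSE)
    configs <- c(configs, cs)
    ks <- c(ks, rep(k, length(cs)))
    # uniform over k, uniform within k
    log_prior <- c(log_prior, rep(-log(K) - log(choose(m, k)), length(cs)))
  }
  log_bf <- vapply(configs, function(g) config_log_bf(z, R, g, s = s, n = n),
                   double(1))
  skipped <- is.na(log_bf)
  if (any(skipped)) {
    inform(sprintf("skipped %d configuration(s) with singular LD submatrix.",
                   sum(skipped)))
  }
  lw <- log_prior + log_bf
  lw[skipped] <- -Inf
  post <- exp(lw - logsumexp(lw[!skipped]))
  post[skipped] <- 0

  pip <- numeric(m)
  for (i in seq_along(configs)) {
    pip[configs[[i]]] <- pip[configs[[i]]] + post[i]
  }
  res <- structure(
    list(
      configs = tibble::tibble(config = configs, k = ks, log_bf = log_bf,
                               posterior = post),
      pip = tibble::tibble(variant = ids, pip = pip,
                           in_credible_set = FALSE),
      credible_set = character(0), level = level, coverage = NA_real_,
      k_max = K, s = s, n = n
    ),
    class = "finemap_result"
  )
  cs <- credible_set(res, level = level)
  res$credible_set <- cs
  res$pip$in_credible_set <- ids %in% cs
  res$coverage <- attr(cs, "coverage")
  res
}

#' Minimal credible set of a fine-mapping result
#'
#' Sorts variants by PIP (descending) and returns the smallest prefix whose
#' configuration coverage — the summed posterior of configurations
#' containing at least one member of the prefix — reaches `level`. For a
#' single causal variant (K = 1) this is exactly the summed PIP; for K > 1
#' it implements the "jointly covering" reading. Ties at the boundary are
#' resolved deterministically in variant order, keeping the set minimal.
#'
#' @param result A `finemap_result` from [enumerate_posteriors()].
#' @param level Required coverage (default 0.95).
#' @return Character vector of member variant IDs, with attribute
#'   `coverage`.
#' @export
credible_set <- function(result, level = 0.95) {
  stopifnot(inherits(result, "finemap_result"))
  pip <- result$pip$pip
  ids <- result$pip$variant
  post <- result$configs$posterior
  configs <- result$configs$config
  ord <- order(pip, decreasing = TRUE)
  covered <- rep(FALSE, length(post))
  cov_total <- 0
  take <- 0L
  for (i in ord) {
    take <- take + 1L
    hit <- !covered & vapply(configs, function(g) i %in% g, logical(1))
    covered <- covered | hit
    cov_total <- sum(post[covered])
    if (cov_total >= level - 1e-12) break
  }
  chosen <- ord[seq_len(take)]
  out <- ids[sort(chosen)]
  attr(out, "coverage") <- cov_total
  out
}

#' @export
print.finemap_result <- function(x, ...) {
  cat(sprintf(
    "<finemap_result> %d variants, K = %d, prior SD %.3g, n = %d\n",
    nrow(x$pip), x$k_max, x$s, x$n
  ))
  cat(sprintf("%d%% credible set: %d variant(s), coverage %.4f\n",
              round(100 * x$level), length(x$credible_set), x$coverage))
  invisible(x)
}

#' Fine-map a region from individual-level data
#'
#' Convenience wrapper: computes z-scores and the in-sample LD matrix from
#' a genotype matrix restricted to a region, then enumerates posteriors.
#' LD is computed from the same samples used for association, as in the
#' discovery analysis.
#'
#' @param G A [geno_matrix()] (or dosage matrix) restricted to the region.
#' @param y Adjusted phenotype.
#' @param K Maximum number of causal variants.
#' @inheritParams enumerate_posteriors
#' @return A `finemap_result`.
#' @export
finemap_region <- function(G, y, K, s = 0.08, level = 0.95, max_configs = 2e6) {
  X <- as_dosage_matrix(G)
  sc <- fast_marginal_scan(X, y)
  keep <- !sc$monomorphic
  X <- X[, keep, drop = FALSE]
  z <- sc$beta[keep] / sc$se[keep]
  R <- cor(X)
  enumerate_posteriors(z, R, K = K, s = s, n = nrow(X), level = level,
                       variant_ids = colnames(X), max_configs = max_configs)
}
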