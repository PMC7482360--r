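# Independent oracles and fixture builders used across the suite.

# Quick cohort: independent variants (one per block) unless span given.
make_cohort <- function(n, m, seed, span = 1L, causal = NULL, h2 = 0, ...) {
  cfg <- sim_config(n_samples = n, n_variants = m, ld_block_span = span,
                    causal_spec = causal, h2_polygenic = h2, seed = seed, ...)
  G <- simulate_genotypes(cfg)
  list(G = G, y = simulate_phenotype(G, cfg), cfg = cfg)
}

# Naive stepwise selector driven entirely by lm()/summary() — an
# implementation of the same add/remove rules through a different code
# path, used as the oracle for the fast FWL implementation.
naive_stepwise <- function(X, y, thr, r2skip = 0.9) {
  m <- ncol(X)
  up <- vapply(seq_len(m), function(j) {
    summary(lm(y ~ X[, j]))$coefficients[2, 4]
  }, double(1))
  if (min(up) > thr) return(integer(0))
  M <- which.min(up)
  repeat {
    cand <- setdiff(seq_len(m), M)
    if (length(cand) > 0) {
      keep <- vapply(cand, function(j) {
        all(cor(X[, j], X[, M, drop = FALSE])^2 <= r2skip)
      }, logical(1))
      cand <- cand[keep]
    }
    if (length(cand) == 0) break
    pad <- vapply(cand, function(j) {
      cf <- summary(lm(y ~ X[, c(M, j)]))$coefficients
      cf[nrow(cf), 4]
    }, double(1))
    if (min(pad) > thr) break
    M <- c(M, cand[which.min(pad)])
    repeat {
      cf <- summary(lm(y ~ X[, M, drop = FALSE]))$coefficients
      pd <- cf[-1, 4]
      if (max(pd) < thr) break
      M <- M[-which.max(pd)]
      if (length(M) == 0) return(integer(0))
    }
  }
  sort(M)
}

# Physicists' Gauss-Hermite rule by Golub-Welsch.
gh_rule <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Multivariate normal log-density via solve()/determinant() — deliberately
# a different linear-algebra path than the package's Cholesky backsolve.
ldmvn_solve <- function(x, mu, sigma) {
  k <- length(x)
  d <- x - mu
  -0.5 * k * log(2 * pi) -
    0.5 * as.numeric(determinant(sigma, logarithm = TRUE)$modulus) -
    0.5 * sum(d * solve(sigma, d))
}

# Bayes factor of a causal configuration by Gauss-Hermite quadrature over
# the effect prior: z_g | lambda ~ N(R_g lambda, R_g), lambda ~ N(0, n s^2 I).
quadrature_bf <- function(z, R, config, s, n, k_nodes = 48) {
  Rg <- R[config, config, drop = FALSE]
  zg <- z[config]
  d <- length(config)
  rule <- gh_rule(k_nodes)
  sc <- sqrt(2 * n * s^2)
  idx <- do.call(expand.grid, rep(list(seq_len(k_nodes)), d))
  l0 <- ldmvn_solve(zg, rep(0, d), Rg)
  total <- 0
  for (r in seq_len(nrow(idx))) {
    ii <- as.integer(idx[r, ])
    lam <- sc * rule$nodes[ii]
    w <- prod(rule$weights[ii]) / pi^(d / 2)
    total <- total + w * exp(ldmvn_solve(zg, as.vector(Rg %*% lam), Rg) - l0)
  }
  total
}
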