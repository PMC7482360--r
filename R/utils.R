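# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom stats pnorm qnorm pt rnorm rbinom runif var sd cor lm glm
#'   binomial coef residuals uniroot plogis rmultinom quantile complete.cases
#'   wilcox.test ks.test shapiro.test fisher.test binom.test AIC logLik
#'   predict setNames median rlnorm
#' @importFrom utils combn head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Log-density of a zero-mean multivariate normal, via Cholesky.
# Returns NA (with no error) when sigma is not positive definite.
ldmvnorm0 <- function(x, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  k <- length(x)
  q <- backsolve(ch, x, transpose = TRUE)
  -0.5 * k * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(q^2)
}

# Rank-scale each column of a numeric matrix to (0, 1); used so greedy
# matching treats covariates on comparable scales.
rank_scale <- function(m) {
  apply(m, 2L, function(col) rank(col, ties.method = "average") / (length(col) + 1))
}
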