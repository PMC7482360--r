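# Discovery-saturation modeling: fit four candidate growth curves to
# (sample size, discovery count or heritability) points and select the best
# by small-sample-corrected AIC.

saturation_forms <- list(
  linear = .y ~ .x,
  sqrt = .y ~ sqrt(.x),
  sqrt_linear = .y ~ sqrt(.x) + .x,
  log = .y ~ log(.x)
)

# AICc = AIC + 2k(k+1)/(n-k-1) with k the number of regression
# coefficients (error variance profiled out of the correction). The form
# is undefined (treated as +Inf, hence ineligible) when the correction
# denominator is non-positive: with only four cohorts this excludes the
# saturated three-coefficient sqrt+linear form, which would otherwise win
# trivially by interpolating the points.
aicc <- function(fit) {
  k <- length(coef(fit))
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(Inf)
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit discovery-saturation models
#'
#' Fits the four candidate growth models `y ~ x`, `y ~ sqrt(x)`,
#' `y ~ sqrt(x) + x` and `y ~ log(x)` to (cohort size, discovery) points by
#' least squares and selects the best-fitting form by AICc. All four fits
#' are reported.
#'
#' @param x Cohort sample sizes; strictly increasing and positive.
#' @param y Discovery measure at each cohort size (count of independent
#'   variants, genes or loci, or heritability explained).
#' @return A `saturation_fit`: tibble with one row per model (`model`,
#'   `rss`, `aicc`, `selected`, `coefficients` list column); attributes
#'   `x`, `y`, `fits` (the lm objects) and `selected`.
#' @export
fit_saturation_models <- function(x, y) {
  if (length(x) < 4 || length(y) != length(x)) {
    abort("need at least 4 (x, y) points (one per cohort).")
  }
  if (any(x <= 0)) abort("`x` must be positive (log and sqrt forms).")
  if (any(diff(x) <= 0)) abort("`x` must be strictly increasing.")
  df <- data.frame(.x = x, .y = y)
  fits <- lapply(saturation_forms, function(f) lm(f, data = df))
  tbl <- tibble::tibble(
    model = names(fits),
    rss = vapply(fits, function(f) sum(residuals(f)^2), double(1)),
    aicc = vapply(fits, aicc, double(1)),
    coefficients = lapply(fits, coef)
  )
  tbl$selected <- seq_len(nrow(tbl)) == which.min(tbl$aicc)
  attr(tbl, "x") <- x
  attr(tbl, "y") <- y
  attr(tbl, "fits") <- fits
  attr(tbl, "selected") <- tbl$model[tbl$selected]
  class(tbl) <- c("saturation_fit", class(tbl))
  tbl
}

#' Project discoveries at a new cohort size
#'
#' Evaluates the selected saturation model at `n_new`, and also reports the
#' naive linear projection through the first three observed points for
#' comparison with the full fit.
#'
#' @param fit A `saturation_fit` from [fit_saturation_models()].
#' @param n_new New cohort size(s), positive.
#' @return Tibble `n_new`, `predicted` (selected model),
#'   `linear_projection` (line fitted to the first 3 points), `model`.
#' @export
project_discovery <- function(fit, n_new) {
  stopifnot(inherits(fit, "saturation_fit"))
  if (any(n_new <= 0)) abort("`n_new` must be positive.")
  sel <- attr(fit, "selected")
  lmfit <- attr(fit, "fits")[[sel]]
  pred <- predict(lmfit, newdata = data.frame(.x = n_new))
  x <- attr(fit, "x"); y <- attr(fit, "y")
  lin3 <- lm(.y ~ .x, data = data.frame(.x = x[1:3], .y = y[1:3]))
  tibble::tibble(
    n_new = n_new,
    predicted = unname(pred),
    linear_projection = unname(predict(lin3, newdata = data.frame(.x = n_new))),
    model = sel
  )
}
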