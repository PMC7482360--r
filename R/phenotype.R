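# Phenotype preparation: extreme-value exclusions, derived white-cell
# subtype counts, covariate adjustment and rank-based inverse-normal
# transformation of blood-count traits.

# Clinical extreme-measurement thresholds above which a sample is excluded.
# Units: wbc 10^9/L, hgb g/dL, hct %, plt 10^9/L.
blood_extreme_thresholds <- c(wbc = 200, hgb = 20, hct = 60, plt = 1000)

#' Flag samples with extreme blood-count measurements
#'
#' Applies the standard full-blood-count extreme-value exclusions:
#' WBC > 200 x 10^9/L, hemoglobin > 20 g/dL, hematocrit > 60%,
#' platelets > 1000 x 10^9/L. Samples exceeding any threshold on the trait
#' columns present in the table are flagged; nothing is dropped, so clinical
#' or medication exclusions supplied by the user (as a pre-existing
#' `excluded` column) compose with these flags.
#'
#' @param table Data frame with any of the columns `wbc`, `hgb`, `hct`,
#'   `plt` in the units above, and optionally a logical `excluded` column.
#' @return The table as a tibble with an `excluded` column; attribute
#'   `exclusion_counts` gives the number of samples newly flagged per trait.
#' @export
apply_extreme_filters <- function(table) {
  table <- tibble::as_tibble(table)
  traits <- intersect(names(blood_extreme_thresholds), names(table))
  excluded <- if ("excluded" %in% names(table)) table$excluded else rep(FALSE, nrow(table))
  counts <- integer(0)
  for (tr in traits) {
    v <- table[[tr]]
    if (any(v < 0, na.rm = TRUE)) {
      abort(sprintf("negative values in trait column `%s`.", tr))
    }
    hit <- !is.na(v) & v > blood_extreme_thresholds[[tr]]
    counts[tr] <- sum(hit & !excluded)
    excluded <- excluded | hit
  }
  table$excluded <- excluded
  attr(table, "exclusion_counts") <- counts
  table
}

#' Derive an absolute white-cell subtype count
#'
#' The relative count of a white-cell subtype (e.g. basophils) is the total
#' WBC count multiplied by the subtype proportion; the result carries WBC
#' units (10^9/L).
#'
#' @param wbc_total Total white-blood-cell count (10^9/L).
#' @param proportion Subtype proportion in `[0, 1]` (a percentage divided
#'   by 100).
#' @return Numeric subtype count, same length as the inputs.
#' @export
derive_subtype_counts <- function(wbc_total, proportion) {
  if (any(proportion < 0 | proportion > 1, na.rm = TRUE)) {
    abort("`proportion` must be in [0, 1].")
  }
  wbc_total * proportion
}

#' Rank-based inverse-normal transform
#'
#' Maps values to standard normal quantiles via their ranks using the Blom
#' offset: `z_i = qnorm((r_i - 3/8) / (n + 1/4))` with tie-averaged ranks,
#' so tied inputs receive equal z-scores and the map is order-preserving.
#'
#' @param values Numeric vector with at least 3 finite values, not all
#'   equal. `NA`s are propagated.
#' @return Numeric vector of z-scores.
#' @export
inverse_normal_transform <- function(values) {
  ok <- is.finite(values)
  x <- values[ok]
  if (length(x) < 3L) abort("need at least 3 finite values.")
  if (diff(range(x)) == 0) abort("all values are equal; cannot rank-transform.")
  r <- rank(x, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}

#' Adjust a trait for covariates and inverse-normalize the residuals
#'
#' Regresses the (optionally log10-transformed) trait on the covariates by
#' ordinary least squares and applies the rank-based inverse-normal
#' transform to the residuals — the standard preparation of blood-count
#' phenotypes for association testing. WBC-related traits are conventionally
#' log10-transformed first (`log10_transform = TRUE`).
#'
#' @param table Data frame holding the trait and covariate columns.
#' @param trait Name of the trait column.
#' @param covariates Character vector of covariate column names (e.g. age,
#'   age squared, sex, principal components); may be empty.
#' @param log10_transform Log10-transform the trait before regression;
#'   requires strictly positive values.
#' @return Numeric vector of transformed residuals (mean 0, variance close
#'   to 1), aligned with the rows of `table`.
#' @export
adjust_and_normalize <- function(table, trait, covariates = character(),
                                 log10_transform = FALSE) {
  table <- tibble::as_tibble(table)
  if (!trait %in% names(table)) abort(sprintf("unknown trait column `%s`.", trait))
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov) > 0) {
    abort(sprintf("unknown covariate column(s): %s.", paste(missing_cov, collapse = ", ")))
  }
  y <- table[[trait]]
  if (log10_transform) {
    if (any(y <= 0, na.rm = TRUE)) {
      abort("log10 transform requires strictly positive trait values.")
    }
    y <- log10(y)
  }
  if (length(covariates) > 0) {
    df <- data.frame(.y = y, table[covariates])
    fit <- lm(.y ~ ., data = df, na.action = stats::na.exclude)
    res <- residuals(fit)
  } else {
    res <- y - mean(y, na.rm = TRUE)
  }
  if (sd(res, na.rm = TRUE) < 1e-12 || all(!is.finite(res))) {
    abort("constant residuals; trait is fully explained by the covariates.")
  }
  inverse_normal_transform(res)
}
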