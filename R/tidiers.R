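# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_histogram geom_vline labs theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @rdname stepwise_select
#' @param x A `sentinel_set`.
#' @param ... Unused.
#' @export
tidy.sentinel_set <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname stepwise_select
#' @export
glance.sentinel_set <- function(x, ...) {
  tibble::tibble(
    n_selected = nrow(x),
    n_samples = attr(x, "n"),
    p_threshold = attr(x, "p_threshold"),
    min_joint_p = if (nrow(x) > 0) min(x$p) else NA_real_
  )
}

#' @rdname enumerate_posteriors
#' @param x A `finemap_result`.
#' @param ... Unused.
#' @export
tidy.finemap_result <- function(x, ...) {
  x$pip
}

#' @rdname enumerate_posteriors
#' @export
glance.finemap_result <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x$pip), k_max = x$k_max,
    n_configs = nrow(x$configs), credible_set_size = length(x$credible_set),
    coverage = x$coverage, level = x$level, prior_sd = x$s, n = x$n
  )
}

#' @rdname overlap_enrichment
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, null_mean = x$null_mean,
    fold_enrichment = x$fold_enrichment, p_value = x$p_value,
    n_perm = x$n_perm
  )
}

#' @rdname overlap_enrichment
#' @export
glance.enrichment_result <- function(x, ...) tidy.enrichment_result(x)

#' @rdname fit_saturation_models
#' @param x A `saturation_fit`.
#' @param ... Unused.
#' @export
tidy.saturation_fit <- function(x, ...) {
  purrr::map2_dfr(x$model, x$coefficients, function(m, cf) {
    tibble::tibble(model = m, term = names(cf), estimate = unname(cf))
  })
}

#' @rdname fit_saturation_models
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble::tibble(
    selected = attr(x, "selected"),
    n_points = length(attr(x, "x")),
    rss_selected = x$rss[x$selected],
    aicc_selected = x$aicc[x$selected]
  )
}

#' Plot posterior inclusion probabilities of a fine-mapped region
#'
#' @param object A `finemap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.finemap_result <- function(object, ...) {
  d <- object$pip
  d$index <- seq_len(nrow(d))
  ggplot(d, aes(x = .data$index, y = .data$pip,
                colour = .data$in_credible_set)) +
    geom_point(size = 2) +
    labs(x = "variant", y = "posterior inclusion probability",
         colour = sprintf("in %d%% credible set", round(100 * object$level))) +
    theme_minimal()
}

#' Plot observed and fitted discovery-saturation curves
#'
#' @param object A `saturation_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saturation_fit <- function(object, ...) {
  x <- attr(object, "x"); y <- attr(object, "y")
  grid <- seq(min(x), max(x), length.out = 100)
  fits <- attr(object, "fits")
  curves <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(model = nm, x = grid,
                   y = predict(f, newdata = data.frame(.x = grid)))
  })
  ggplot() +
    geom_line(data = curves, aes(x = .data$x, y = .data$y,
                                 colour = .data$model)) +
    geom_point(data = tibble::tibble(x = x, y = y),
               aes(x = .data$x, y = .data$y), size = 2) +
    labs(x = "cohort size", y = "discoveries",
         subtitle = sprintf("selected: %s", attr(object, "selected"))) +
    theme_minimal()
}

#' Plot the permutation null of an enrichment result
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot(tibble::tibble(null = object$null), aes(x = .data$null)) +
    geom_histogram(bins = 30, fill = "grey70") +
    geom_vline(xintercept = object$observed, colour = "red") +
    labs(x = "null overlap", y = "permutations",
         subtitle = sprintf("FE = %.2f, p = %.3g",
                            object$fold_enrichment, object$p_value)) +
    theme_minimal()
}

#' Compare polygenic-score strategies
#'
#' Bar chart of variance explained per selection strategy.
#'
#' @param evals Tibble with columns `strategy` and `r_squared` (one row per
#'   evaluated model, e.g. from binding [evaluate_pgs()] results).
#' @return A ggplot.
#' @export
plot_pgs_strategies <- function(evals) {
  ggplot(tibble::as_tibble(evals),
         aes(x = .data$strategy, y = .data$r_squared)) +
    geom_col(fill = "steelblue") +
    labs(x = "selection strategy", y = expression(R^2)) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
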