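# broom-style tidiers for the package's fitted objects.

#' Tidy a monoexponential fit
#'
#' @param x A `mono_fit` from [fit_monoexponential()].
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`.
#' @export
tidy.mono_fit <- function(x, ...) {
  tibble(term = c("k", "plateau"), estimate = c(x$k, x$plateau))
}

#' @rdname tidy.mono_fit
#' @return `glance()` returns a one-row tibble with `k`, `plateau`, `rss`,
#'   `n_points`, `status`.
#' @export
glance.mono_fit <- function(x, ...) {
  tibble(
    k = x$k, plateau = x$plateau, rss = x$rss,
    n_points = x$n_points, status = x$status
  )
}

#' Aggregate view of a specificity table
#'
#' @param x A [pairwise_ratios()] result.
#' @param ... Unused.
#' @return One-row tibble: the class pair, both aggregation conventions
#'   (mean of per-context ratios, ratio of class means), the median ratio
#'   and the count of excluded (infinite/undefined) contexts.
#' @export
glance.specificity_table <- function(x, ...) {
  tibble(
    pair = paste(attr(x, "pair"), collapse = "/"),
    mean_of_ratios = attr(x, "mean_of_ratios"),
    ratio_of_means = attr(x, "ratio_of_means"),
    median_ratio = median(x$ratio, na.rm = TRUE),
    n_contexts = nrow(x),
    n_excluded = attr(x, "n_excluded")
  )
}

#' Tidy an enzyme comparison
#'
#' @param x A [compare_enzymes()] result.
#' @param ... Unused.
#' @return `tidy()` returns the per-context table (`context`, `s_a`, `s_b`,
#'   `fold`); `glance()` the geometric-mean fold change and paired t-test.
#' @export
tidy.enzyme_comparison <- function(x, ...) {
  x$table
}

#' @rdname tidy.enzyme_comparison
#' @export
glance.enzyme_comparison <- function(x, ...) {
  tibble(
    pair = paste(x$pair, collapse = "/"),
    geometric_mean_fold = x$geometric_mean_fold,
    t_statistic = x$t_statistic,
    df = x$df,
    p_value = x$p_value,
    n_contexts = nrow(x$table)
  )
}

#' Tidy a randomization correlation test
#'
#' @param x A `correlation_test` from [randomization_pvalue()] or
#'   [correlation_difference_test()].
#' @param ... Unused.
#' @return One-row tibble with the observed statistic, null mean/SD, Z, p,
#'   shuffle count and seed.
#' @export
tidy.correlation_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    observed = x$r_observed,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    z = x$z,
    p_value = x$p,
    n_shuffles = x$n_shuffles,
    n_contexts = x$n_contexts,
    seed = x$seed,
    low_confidence = x$low_confidence
  )
}
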