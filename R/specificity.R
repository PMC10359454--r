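# Pairwise substrate-specificity ratios and their energetic interpretation.

#' Per-context specificity ratios between two substrate classes
#'
#' Joins the rate constants of an ordered class pair (x, y) per NNCGNN
#' context and computes r = k_x / k_y. Both aggregation conventions are
#' reported side by side as attributes: the mean of per-context ratios and
#' the ratio of class means (they differ for skewed rate distributions and
#' neither is privileged). Undefined ratios (k_y = 0) are flagged infinite
#' and excluded from the aggregates with a count, never silently dropped.
#'
#' @param rates Rate table (`substrate_class`, `context`, `k`).
#' @param pair Ordered character pair, e.g. `c("HM", "UM")`.
#' @return Tibble of class `specificity_table`: `context`, `k_x`, `k_y`,
#'   `ratio`, `flag` (`"ok"`, `"infinite"` or `"undefined"`); attributes
#'   `pair`, `mean_of_ratios`, `ratio_of_means`, `n_excluded`. See
#'   [glance.specificity_table()].
#' @export
pairwise_ratios <- function(rates, pair = c("HM", "UM")) {
  stopifnot(length(pair) == 2L)
  x <- filter(rates, substrate_class == pair[1]) %>% select(context, k_x = k)
  y <- filter(rates, substrate_class == pair[2]) %>% select(context, k_y = k)
  if (nrow(x) == 0L || nrow(y) == 0L) {
    abort(sprintf("no rates for class pair (%s, %s)", pair[1], pair[2]))
  }
  tab <- inner_join(x, y, by = "context") %>%
    mutate(
      ratio = k_x / k_y,
      flag = case_when(
        !is.finite(k_x) | !is.finite(k_y) ~ "undefined",
        k_y == 0 ~ "infinite",
        TRUE ~ "ok"
      ),
      ratio = ifelse(flag == "ok", ratio, NA_real_)
    )
  finite <- filter(tab, flag == "ok")
  attr(tab, "pair") <- pair
  attr(tab, "mean_of_ratios") <- mean(finite$ratio)
  attr(tab, "ratio_of_means") <- mean(finite$k_x) / mean(finite$k_y)
  attr(tab, "n_excluded") <- sum(tab$flag != "ok")
  class(tab) <- c("specificity_table", class(tab))
  tab
}

#' Summarize a specificity-ratio distribution
#'
#' Box-plot style summary of the finite per-context ratios: median, first
#' and third quartile (linear-interpolation quartiles, [stats::quantile()]
#' type 7), whiskers at 1.5 IQR clipped to the data, outliers beyond the
#' whiskers, and the extreme contexts (argmin/argmax).
#'
#' @param table A [pairwise_ratios()] result (or any tibble with `context`
#'   and `ratio`).
#' @return One-row tibble: `n`, `mean`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `n_outliers`, `min`, `max`, `argmin`, `argmax`, plus an
#'   `outliers` list-column of outlier contexts.
#' @export
summarize_ratios <- function(table) {
  finite <- filter(table, is.finite(ratio))
  if (nrow(finite) == 0L) abort("no finite ratios to summarize")
  r <- finite$ratio
  q <- quantile(r, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  whisker_lo <- min(r[r >= lo_fence])
  whisker_hi <- max(r[r <= hi_fence])
  out_idx <- r < lo_fence | r > hi_fence
  tibble(
    n = length(r),
    mean = mean(r),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    whisker_lo = whisker_lo,
    whisker_hi = whisker_hi,
    n_outliers = sum(out_idx),
    min = min(r),
    max = max(r),
    argmin = finite$context[which.min(r)],
    argmax = finite$context[which.max(r)],
    outliers = list(finite$context[out_idx])
  )
}

#' Compare the specificity of two enzymes
#'
#' Computes the per-context specificity ratio (class pair x/y) for each
#' enzyme's rate table, the per-context fold change enzyme A / enzyme B, the
#' geometric-mean fold change, and a two-sided paired t-test on the
#' natural-log specificity ratios (ratio data carry multiplicative noise,
#' so the test runs on the log scale). When the two enzymes are identical
#' the log differences have zero variance and the p-value is reported as 1
#' by convention.
#'
#' @param a,b Rate tables for the two enzymes (same 256 contexts).
#' @param pair Ordered class pair for the specificity (default
#'   `c("HM", "UM")`).
#' @return Object of class `enzyme_comparison`: list with `table` (tibble:
#'   `context`, `s_a`, `s_b`, `fold`), `geometric_mean_fold`, `t_statistic`,
#'   `p_value`, `df`, `pair`. [tidy()] and [glance()] methods are
#'   available.
#' @export
compare_enzymes <- function(a, b, pair = c("HM", "UM")) {
  ra <- pairwise_ratios(a, pair) %>% select(context, s_a = ratio)
  rb <- pairwise_ratios(b, pair) %>% select(context, s_b = ratio)
  missing_a <- setdiff(nncgnn_contexts(), ra$context)
  missing_b <- setdiff(nncgnn_contexts(), rb$context)
  if (length(missing_a) || length(missing_b)) {
    abort(sprintf(
      "missing contexts in enzyme tables (a: %d, b: %d)",
      length(missing_a), length(missing_b)
    ))
  }
  tab <- inner_join(as_tibble(ra), as_tibble(rb), by = "context") %>%
    filter(is.finite(s_a), is.finite(s_b), s_a > 0, s_b > 0) %>%
    mutate(fold = s_a / s_b)

  logdiff <- log(tab$s_a) - log(tab$s_b)
  gm_fold <- exp(mean(logdiff))
  if (sd(logdiff) <= 1e-10 * max(1, abs(mean(logdiff)))) {
    # constant log fold change: p = 1 by convention when the enzymes are
    # identical, and the no-variance limit of the t-test (p -> 0) otherwise
    same <- abs(mean(logdiff)) <= 1e-12
    t_stat <- if (same) 0 else sign(mean(logdiff)) * Inf
    p <- if (same) 1 else 0
    df <- length(logdiff) - 1L
  } else {
    tt <- t.test(log(tab$s_a), log(tab$s_b), paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    df <- unname(tt$parameter)
  }
  structure(
    list(
      table = tab, geometric_mean_fold = gm_fold,
      t_statistic = t_stat, p_value = p, df = df, pair = pair
    ),
    class = "enzyme_comparison"
  )
}

#' @export
print.enzyme_comparison <- function(x, ...) {
  cat(sprintf(
    "<enzyme_comparison> %s/%s specificity, %d contexts\n  geometric-mean fold (A/B): %.3g; paired t on log ratios: t = %.3g, p = %.3g\n",
    x$pair[1], x$pair[2], nrow(x$table), x$geometric_mean_fold,
    x$t_statistic, x$p_value
  ))
  invisible(x)
}

#' Transition-state energy difference implied by a rate ratio
#'
#' Converts a rate (or specificity) ratio into the corresponding difference
#' in transition-state free energy, `R * T * ln(ratio)`, in kJ/mol. A
#' 100-fold rate preference at 298 K corresponds to about 11 kJ/mol.
#'
#' @param ratio Positive rate ratio (vectorized).
#' @param temperature Temperature in K (default 298).
#' @param gas_constant Gas constant in J/(mol K) (default 8.314).
#' @return Numeric vector, kJ/mol.
#' @export
#' @examples
#' delta_g(100)
delta_g <- function(ratio, temperature = 298, gas_constant = 8.314) {
  if (any(ratio <= 0)) abort("`ratio` must be positive")
  if (temperature <= 0) abort("`temperature` must be positive (K)")
  gas_constant * temperature * log(ratio) / 1000
}

#' Hydrophobic burial energy of a surface area
#'
#' Energy associated with burying hydrophobic surface area, `area x
#' coefficient / 1000` in kJ/mol. With the solvent-accessible surface of a
#' pyrimidine C5-methyl group in DNA (30.3 square Angstrom) and a burial
#' coefficient of 60.8 J/(mol x square Angstrom) this yields about
#' 1.9 kJ/mol.
#'
#' @param area Buried surface area in square Angstrom (vectorized).
#' @param coefficient Burial energy coefficient in J/(mol x square
#'   Angstrom) (default 60.8).
#' @return Numeric vector, kJ/mol.
#' @export
#' @examples
#' burial_energy(30.3)
burial_energy <- function(area, coefficient = 60.8) {
  if (any(area < 0)) abort("`area` must be >= 0")
  if (coefficient < 0) abort("`coefficient` must be >= 0")
  area * coefficient / 1000
}
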