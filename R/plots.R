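# ggplot2 visualizations of the main result types.

#' Plot an observed/expected flanking preference profile
#'
#' Lines of o/e ratio per flanking position, one panel per base, separately
#' for the methylated and unmethylated read subsets; values above 1 mark
#' favored bases.
#'
#' @param object An [oe_profile()] tibble.
#' @param positions Positions to display (default -4..+4, where the largest
#'   effects live).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oe_profile <- function(object, positions = -4:4, ...) {
  df <- object %>%
    filter(position %in% positions) %>%
    tidyr::pivot_longer(
      dplyr::any_of(c("oe_meth", "oe_unmeth")),
      names_to = "subset", values_to = "oe"
    ) %>%
    mutate(subset = dplyr::recode(subset,
      oe_meth = "methylated", oe_unmeth = "unmethylated"
    ))
  ggplot2::ggplot(df, ggplot2::aes(position, oe, colour = subset)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~base, nrow = 1) +
    ggplot2::labs(
      x = "flanking position (CpG between -1 and +1)",
      y = "observed / expected", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-class rate distributions
#'
#' Box plots (median, quartiles, 1.5 IQR whiskers, outlier dots) of the 256
#' per-context rate constants per substrate class, on a log axis.
#'
#' @param object A `rate_table` from [scale_and_merge()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_table <- function(object, ...) {
  df <- filter(as_tibble(object), is.finite(k), k > 0)
  ggplot2::ggplot(df, ggplot2::aes(substrate_class, k)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "rate constant k (per unit dose)") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-context rates
#'
#' 16 x 16 tile map of the 256 NNCGNN rate constants of one substrate class,
#' 5' dinucleotide by 3' dinucleotide.
#'
#' @param rates Rate table (optionally several classes; faceted).
#' @return A ggplot object.
#' @export
plot_rate_heatmap <- function(rates) {
  df <- rates %>%
    as_tibble() %>%
    mutate(
      x5 = substr(context, 1, 2),
      x3 = substr(context, 5, 6)
    )
  ggplot2::ggplot(df, ggplot2::aes(x3, x5, fill = log10(k))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~substrate_class) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "3' NN", y = "5' NN", fill = "log10 k") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 6))
}

#' Plot a specificity-ratio distribution
#'
#' @param object A [pairwise_ratios()] table.
#' @param ... Unused.
#' @return A ggplot object (box plot of per-context ratios, log axis).
#' @export
autoplot.specificity_table <- function(object, ...) {
  pair <- paste(attr(object, "pair"), collapse = "/")
  df <- filter(as_tibble(object), is.finite(ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = pair, y = ratio)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "per-context specificity ratio") +
    ggplot2::theme_minimal()
}

#' Plot a randomization test against its null
#'
#' @param object A `correlation_test`.
#' @param ... Unused.
#' @return A ggplot object: histogram placeholder of the null summary with
#'   the observed statistic marked.
#' @export
autoplot.correlation_test <- function(object, ...) {
  null_df <- tibble(
    value = c(
      object$null_mean - 2 * object$null_sd,
      object$null_mean,
      object$null_mean + 2 * object$null_sd
    ),
    what = c("null -2 SD", "null mean", "null +2 SD")
  )
  ggplot2::ggplot(null_df, ggplot2::aes(value, 0)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(
        xmin = object$null_mean - 2 * object$null_sd,
        xmax = object$null_mean + 2 * object$null_sd, y = 0
      ),
      height = 0.1
    ) +
    ggplot2::geom_point(
      data = tibble(value = object$r_observed),
      ggplot2::aes(value, 0),
      colour = "red", size = 3
    ) +
    ggplot2::annotate("text",
      x = object$r_observed, y = 0.2,
      label = sprintf("observed (Z = %.1f)", object$z)
    ) +
    ggplot2::ylim(-0.5, 0.5) +
    ggplot2::labs(x = object$statistic, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      axis.ticks.y = ggplot2::element_blank()
    )
}
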