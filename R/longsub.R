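# Multi-CpG substrate analysis: group reaction-progress fits for
# hemimethylated vs unmethylated sites and the observed-vs-expected
# specificity comparison against the single-site rate table.

#' Average methylation rates per site group on long substrates
#'
#' Groups per-site methylation series by substrate label and lower-strand
#' state (e.g. HM-substrate sites, UM-substrate sites, patterned-substrate
#' hemimethylated and unmethylated sites), pools the per-dose fractions as
#' read-weighted means, and fits one monoexponential reaction-progress curve
#' per group.
#'
#' @param series Site-series tibble ([simulate_long_kinetics()] output or
#'   equivalent): `substrate`, `position`, `context`, `lower_state`, `dose`,
#'   `n_meth`, `n_total`.
#' @param plateau Plateau passed to [fit_monoexponential()] (default 1).
#' @return Tibble with one row per (substrate, lower_state) group: `k`,
#'   `rss`, `n_points`, `status`, `n_sites`.
#' @export
group_rates <- function(series, plateau = 1) {
  groups <- series %>%
    group_by(substrate, lower_state)
  empty <- dplyr::group_keys(groups)[integer(0), ]

  out <- groups %>%
    summarise(
      n_sites = dplyr::n_distinct(position),
      fit = list({
        pooled <- tibble(dose = dose, n_meth = n_meth, n_total = n_total) %>%
          group_by(dose) %>%
          summarise(
            fraction = sum(n_meth) / sum(n_total),
            n_reads = sum(n_total), .groups = "drop"
          )
        fit_monoexponential(pooled, plateau = plateau)
      }),
      .groups = "drop"
    ) %>%
    mutate(
      k = purrr::map_dbl(fit, "k"),
      rss = purrr::map_dbl(fit, "rss"),
      n_points = purrr::map_int(fit, "n_points"),
      status = purrr::map_chr(fit, "status")
    ) %>%
    select(substrate, lower_state, k, rss, n_points, status, n_sites)
  out
}

#' Expected group rate from a single-site rate table
#'
#' Arithmetic mean of the per-context rate constants of one substrate class
#' over a set of site contexts, the expectation used when predicting the
#' specificity of a multi-CpG substrate from single-site rates.
#'
#' @param rates Rate table.
#' @param substrate_class Class whose rates to average (`"HM"` or `"UM"`).
#' @param contexts NNCGNN contexts of the sites.
#' @return Scalar mean rate.
#' @export
expected_group_rate <- function(rates, substrate_class, contexts) {
  slice <- filter(
    rates,
    substrate_class == !!substrate_class, context %in% contexts
  )
  missing <- setdiff(contexts, slice$context)
  if (length(missing)) {
    abort(sprintf(
      "contexts missing from rate table: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  # sites can share a context; average over sites, not unique contexts
  k_by_ctx <- setNames(slice$k, slice$context)
  mean(unname(k_by_ctx[contexts]))
}

#' Observed vs expected HM/UM specificity on a long substrate
#'
#' Compares the specificity observed in a long-substrate experiment (ratio
#' of fitted HM-site to UM-site group rates) with the specificity expected
#' from the single-site rate table given the flanking contexts of the sites
#' (mean HM rate over the hemimethylated sites' contexts divided by mean UM
#' rate over the unmethylated sites' contexts). Expected rates can also be
#' supplied directly via `expected_hm`/`expected_um`.
#'
#' @param observed_hm,observed_um Observed group rates (or, equivalently,
#'   already-formed ratios whose quotient is of interest).
#' @param rates Rate table used to compute the expectation (optional if
#'   `expected_hm`/`expected_um` are given).
#' @param hm_sites,um_sites Context vectors of the hemimethylated and
#'   unmethylated sites (used with `rates`).
#' @param expected_hm,expected_um Directly supplied expected rates.
#' @return One-row tibble: `observed_hm`, `observed_um`, `observed_ratio`,
#'   `expected_hm`, `expected_um`, `expected_ratio`, `quotient`
#'   (= observed_ratio / expected_ratio, the relative-specificity
#'   comparison).
#' @export
#' @examples
#' observed_vs_expected(180, 145, expected_hm = 126, expected_um = 102)
observed_vs_expected <- function(observed_hm, observed_um,
                                 rates = NULL, hm_sites = NULL, um_sites = NULL,
                                 expected_hm = NULL, expected_um = NULL) {
  if (is.null(expected_hm)) {
    if (is.null(rates) || is.null(hm_sites)) {
      abort("supply either `rates` + site contexts or `expected_hm`/`expected_um`")
    }
    expected_hm <- expected_group_rate(rates, "HM", hm_sites)
  }
  if (is.null(expected_um)) {
    if (is.null(rates) || is.null(um_sites)) {
      abort("supply either `rates` + site contexts or `expected_hm`/`expected_um`")
    }
    expected_um <- expected_group_rate(rates, "UM", um_sites)
  }
  observed_ratio <- observed_hm / observed_um
  expected_ratio <- expected_hm / expected_um
  tibble(
    observed_hm = observed_hm,
    observed_um = observed_um,
    observed_ratio = observed_ratio,
    expected_hm = expected_hm,
    expected_um = expected_um,
    expected_ratio = expected_ratio,
    quotient = observed_ratio / expected_ratio
  )
}
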