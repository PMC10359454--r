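# Genomic NNCGNN methylation profiles from WGBS-style coverage tables and
# the randomization Z-test relating them to enzyme preference profiles.

#' Per-NNCGNN genomic methylation profile
#'
#' Extracts the NNCGNN flanking context of every covered CpG from the genome,
#' filters sites by read depth (keep coverage strictly greater than
#' `min_coverage`, default 4), and computes the coverage-weighted mean
#' methylation level per context. By default only upper-strand sites are
#' used; with `strand = "both"`, rows flagged as minus-strand (a `strand`
#' column containing `"-"`) are anchored at the G of the upper-strand CpG
#' and use the reverse-complement context. Sites whose position is not a
#' CpG in the genome, or whose flanks contain N or run off the chromosome
#' end, are excluded and counted.
#'
#' @param coverage Coverage tibble (`chrom`, `start`, `end`, `count_meth`,
#'   `count_unmeth`; 1-based inclusive, `start` = position of the C).
#' @param genome Named character vector of chromosome sequences, or a FASTA
#'   path.
#' @param min_coverage Keep sites with coverage > this value (default 4).
#' @param strand `"upper"` (default) or `"both"`.
#' @return Tibble of class `genomic_profile` with one row per NNCGNN
#'   context: `context`, `mean_meth` (weighted mean in \[0, 1\]), `n_sites`,
#'   `total_coverage`, `oe` (context mean / global weighted mean).
#'   Contexts with no qualifying site carry `NA` means. Attribute
#'   `n_excluded` counts non-CpG/edge/N sites.
#' @export
genomic_profile <- function(coverage, genome, min_coverage = 4L,
                            strand = c("upper", "both")) {
  strand <- arg_match(strand)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  missing_chrom <- setdiff(unique(coverage$chrom), names(genome))
  if (length(missing_chrom)) {
    abort(sprintf(
      "chromosome(s) missing from genome: %s",
      paste(missing_chrom, collapse = ", ")
    ))
  }

  cov <- coverage
  if ("strand" %in% names(cov)) {
    if (strand == "upper") {
      cov <- filter(cov, strand != "-")
    }
  } else {
    cov$strand <- "+"
  }
  cov <- mutate(cov, coverage = count_meth + count_unmeth)
  cov <- filter(cov, coverage > min_coverage)

  chrom_len <- setNames(nchar(genome), names(genome))
  pos <- cov$start
  minus <- cov$strand == "-"
  # context of a minus-strand call: the C sits on the lower strand; its
  # upper-strand anchor is the G of the CpG, one base to the right of the
  # lower-strand C's pairing position
  in_range <- pos - 2L >= 1L & pos + 3L <= chrom_len[cov$chrom] &
    !(minus & (pos - 3L < 1L))
  ctx <- rep(NA_character_, nrow(cov))
  plus_rows <- which(!minus & in_range)
  if (length(plus_rows)) {
    ctx[plus_rows] <- substring(
      genome[cov$chrom[plus_rows]],
      pos[plus_rows] - 2L, pos[plus_rows] + 3L
    )
  }
  minus_rows <- which(minus & in_range)
  if (length(minus_rows)) {
    # lower-strand C pairs the upper-strand G at `pos`; upper-strand window
    # for the dyad is (pos-3)..(pos+2), reverse-complemented
    ctx[minus_rows] <- revcomp(substring(
      genome[cov$chrom[minus_rows]],
      pos[minus_rows] - 3L, pos[minus_rows] + 2L
    ))
  }
  valid <- !is.na(ctx) & is_nncgnn(ctx)
  n_excluded <- sum(!valid)
  cov <- cov[valid, ]
  cov$context <- ctx[valid]

  prof <- cov %>%
    group_by(context) %>%
    summarise(
      mean_meth = sum(count_meth) / sum(coverage),
      n_sites = dplyr::n(),
      total_coverage = sum(coverage),
      .groups = "drop"
    )
  global <- sum(cov$count_meth) / sum(cov$coverage)
  out <- tibble(context = nncgnn_contexts()) %>%
    left_join(prof, by = "context") %>%
    mutate(
      n_sites = tidyr::replace_na(n_sites, 0L),
      total_coverage = tidyr::replace_na(total_coverage, 0L),
      oe = mean_meth / global
    )
  attr(out, "n_excluded") <- n_excluded
  attr(out, "global_mean") <- global
  class(out) <- c("genomic_profile", class(out))
  out
}

as_context_vector <- function(x, value_col = NULL) {
  if (is.numeric(x) && !is.null(names(x))) {
    return(x[nncgnn_contexts()])
  }
  if (is.data.frame(x)) {
    if (is.null(value_col)) {
      value_col <- intersect(c("mean_meth", "k", "value"), names(x))[1]
      if (is.na(value_col)) abort("cannot find a value column (mean_meth/k/value)")
    }
    v <- setNames(x[[value_col]], x$context)
    return(v[nncgnn_contexts()])
  }
  abort("expected a named numeric vector or a tibble with a `context` column")
}

#' Pearson correlation of two context profiles
#'
#' Standard product-moment correlation over the 256 NNCGNN contexts,
#' dropping contexts that are missing in either profile pairwise.
#'
#' @param a,b Named numeric vectors over contexts, or tibbles with `context`
#'   and a value column (`mean_meth`, `k` or `value`).
#' @return Pearson r (scalar); `NA` with a warning if fewer than 3 finite
#'   pairs or zero variance.
#' @export
correlate <- function(a, b) {
  va <- as_context_vector(a)
  vb <- as_context_vector(b)
  keep <- is.finite(va) & is.finite(vb)
  if (sum(keep) < 3L) {
    warn("fewer than 3 finite context pairs; correlation undefined")
    return(NA_real_)
  }
  if (sd(va[keep]) == 0 || sd(vb[keep]) == 0) {
    warn("zero variance in a profile; correlation undefined")
    return(NA_real_)
  }
  cor(va[keep], vb[keep])
}

new_correlation_test <- function(statistic, r_observed, null_mean, null_sd,
                                 z, p, n_shuffles, seed, n_contexts,
                                 low_confidence) {
  structure(
    list(
      statistic = statistic, r_observed = r_observed,
      null_mean = null_mean, null_sd = null_sd, z = z, p = p,
      n_shuffles = n_shuffles, seed = seed, n_contexts = n_contexts,
      low_confidence = low_confidence
    ),
    class = "correlation_test"
  )
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf(
    "<correlation_test> %s = %.4f; null %.4f +/- %.4f (%d shuffles); Z = %.2f, p = %.3g%s\n",
    x$statistic, x$r_observed, x$null_mean, x$null_sd, x$n_shuffles,
    x$z, x$p, if (x$low_confidence) " [low confidence: few shuffles]" else ""
  ))
  invisible(x)
}

#' Randomization Z-test of a profile correlation
#'
#' Tests the Pearson correlation between a genomic NNCGNN methylation
#' profile and an enzyme preference profile against a null obtained by
#' randomly reassigning the measured genomic methylation levels to the
#' contexts. The observed r is converted to a Z score against the mean and
#' SD of the shuffled correlations, and p is the upper-tail normal
#' probability (one-sided by default, matching the chance-exceedance
#' question; `two_sided = TRUE` doubles the tail). With the default 20
#' shuffles the p-value is a Z-extrapolation, not an empirical tail
#' frequency; for empirical p-values use `n_shuffles >= 1e4`.
#'
#' @param genomic Genomic profile ([genomic_profile()] tibble or named
#'   vector).
#' @param pref Preference profile (rate-table slice for one class, or named
#'   vector).
#' @param n_shuffles Number of random reassignments (default 20).
#' @param seed Integer seed; the test is fully reproducible given the seed.
#' @param two_sided Two-sided alternative (default `FALSE`).
#' @return A `correlation_test` object; [tidy()] turns it into a one-row
#'   tibble.
#' @export
randomization_pvalue <- function(genomic, pref, n_shuffles = 20L, seed = 1L,
                                 two_sided = FALSE) {
  n_shuffles <- as.integer(n_shuffles)
  if (n_shuffles < 2L) abort("`n_shuffles` must be >= 2")
  vg <- as_context_vector(genomic)
  vp <- as_context_vector(pref)
  keep <- is.finite(vg) & is.finite(vp)
  vg <- vg[keep]
  vp <- vp[keep]
  r_obs <- cor(vg, vp)

  withr::local_seed(seed)
  r_null <- vapply(
    seq_len(n_shuffles),
    function(i) cor(sample(vg), vp),
    numeric(1)
  )
  mu <- mean(r_null)
  sdev <- sd(r_null)
  if (sdev == 0) {
    warn("null SD is zero; p undefined")
    z <- NA_real_
    p <- NA_real_
  } else {
    z <- (r_obs - mu) / sdev
    p <- pnorm(z, lower.tail = FALSE)
    if (two_sided) p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  }
  if (n_shuffles < 10L) {
    inform("fewer than 10 shuffles: Z-based p is low-confidence")
  }
  new_correlation_test(
    "r", r_obs, mu, sdev, z, p, n_shuffles, seed, sum(keep),
    low_confidence = n_shuffles < 10L
  )
}

#' Randomization test of a correlation difference
#'
#' Tests whether the genomic profile correlates better with preference
#' profile `pref_a` than with `pref_b` using the statistic
#' `delta_r = r(genomic, pref_a) - r(genomic, pref_b)`. The null
#' distribution reuses the same genomic shuffles for both correlations, and
#' p is the one-sided upper-tail probability for `delta_r > 0`.
#'
#' @inheritParams randomization_pvalue
#' @param pref_a,pref_b The two preference profiles.
#' @return A `correlation_test` object with statistic `"delta_r"`.
#' @export
correlation_difference_test <- function(genomic, pref_a, pref_b,
                                        n_shuffles = 20L, seed = 1L) {
  n_shuffles <- as.integer(n_shuffles)
  if (n_shuffles < 2L) abort("`n_shuffles` must be >= 2")
  vg <- as_context_vector(genomic)
  va <- as_context_vector(pref_a)
  vb <- as_context_vector(pref_b)
  keep <- is.finite(vg) & is.finite(va) & is.finite(vb)
  vg <- vg[keep]
  va <- va[keep]
  vb <- vb[keep]
  d_obs <- cor(vg, va) - cor(vg, vb)

  withr::local_seed(seed)
  d_null <- vapply(seq_len(n_shuffles), function(i) {
    s <- sample(vg)
    cor(s, va) - cor(s, vb)
  }, numeric(1))
  mu <- mean(d_null)
  sdev <- sd(d_null)
  if (sdev == 0 && d_obs == mu) {
    # identical preference profiles: the statistic is identically zero and
    # the test is exactly indifferent
    z <- 0
    p <- 0.5
  } else if (sdev == 0) {
    warn("null SD is zero; p undefined")
    z <- NA_real_
    p <- NA_real_
  } else {
    z <- (d_obs - mu) / sdev
    p <- pnorm(z, lower.tail = FALSE)
  }
  new_correlation_test(
    "delta_r", d_obs, mu, sdev, z, p, n_shuffles, seed, sum(keep),
    low_confidence = n_shuffles < 10L
  )
}
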