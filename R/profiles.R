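# Observed/expected flanking base-composition profiles and context ranking.

window_positions <- function(width) {
  fl <- (width - 2L) %/% 2L
  c(-(fl:1L), 1L:fl) # no position 0; the CpG occupies two unnumbered slots
}

base_counts_by_position <- function(windows) {
  w <- nchar(windows[1])
  m <- seq_to_bytes(windows)
  fl <- (w - 2L) %/% 2L
  keep_rows <- c(seq_len(fl), fl + 2L + seq_len(fl)) # skip the CpG core
  pos <- window_positions(w)
  counts <- matrix(0, nrow = length(pos), ncol = 4L,
    dimnames = list(pos, .BASES)
  )
  for (j in seq_along(.BASE_BYTES)) {
    counts[, j] <- rowSums(m[keep_rows, , drop = FALSE] == .BASE_BYTES[j])
  }
  counts
}

freq_from_counts <- function(counts, pseudo_count) {
  counts <- counts + pseudo_count
  counts / rowSums(counts)
}

#' Observed/expected flanking base-composition profile
#'
#' For one substrate class, computes per position (-flank..-1, +1..+flank)
#' and base the ratio of the base frequency among methylated records to the
#' expected frequency, and the analogous matrix for unmethylated records.
#' The expected frequency comes from the class's full read pool by default
#' (absorbing synthesis bias); `expected = "uniform"` uses 0.25 instead,
#' appropriate for synthetic data with known uniform flanks. A pseudo-count
#' (default 1 per position/base/subset cell) prevents division by zero.
#'
#' @param records Call-record tibble with `flank_window` and `call_upper`
#'   columns (one substrate class).
#' @param expected `"pool"` (default) or `"uniform"`.
#' @param pseudo_count Pseudo-count added per cell (default 1; set 0 for
#'   exact small-sample arithmetic).
#' @return Tibble of class `oe_profile`: `position`, `base`, `oe_meth`,
#'   `oe_unmeth`. The per-position observed frequencies in the numerators
#'   sum to 1.
#' @export
oe_profile <- function(records, expected = c("pool", "uniform"), pseudo_count = 1) {
  expected <- arg_match(expected)
  records <- filter(records, call_upper != "ambiguous", !grepl("N", flank_window))
  meth <- records$flank_window[records$call_upper == "methylated"]
  unmeth <- records$flank_window[records$call_upper == "unmethylated"]
  if (length(meth) == 0L) abort("no methylated records: o/e profile undefined for the methylated subset")
  if (length(unmeth) == 0L) abort("no unmethylated records: o/e profile undefined for the unmethylated subset")

  c_meth <- base_counts_by_position(meth)
  c_unmeth <- base_counts_by_position(unmeth)
  f_meth <- freq_from_counts(c_meth, pseudo_count)
  f_unmeth <- freq_from_counts(c_unmeth, pseudo_count)
  f_exp <- if (expected == "pool") {
    freq_from_counts(c_meth + c_unmeth, pseudo_count)
  } else {
    matrix(0.25,
      nrow = nrow(c_meth), ncol = 4L,
      dimnames = dimnames(c_meth)
    )
  }

  pos <- as.integer(rownames(c_meth))
  out <- tidyr::expand_grid(position = pos, base = .BASES) %>%
    mutate(
      oe_meth = as.vector(t(f_meth / f_exp)),
      oe_unmeth = as.vector(t(f_unmeth / f_exp))
    )
  class(out) <- c("oe_profile", class(out))
  out
}

#' Average o/e profiles across experiments
#'
#' Cell-wise mean and SEM (SD / sqrt(N)) over a list of profiles of
#' identical shape, as used to combine individual time points, experiments
#' and repeats.
#'
#' @param profiles List of [oe_profile()] tibbles with identical
#'   position/base grids.
#' @return An `oe_profile` tibble with `oe_meth`, `oe_unmeth` means and
#'   `sem_meth`, `sem_unmeth` columns.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  ref <- profiles[[1]][, c("position", "base")]
  for (p in profiles) {
    if (!identical(p[, c("position", "base")], ref)) {
      abort("profiles have mismatching position/base grids")
    }
  }
  m_meth <- sapply(profiles, function(p) p$oe_meth)
  m_unmeth <- sapply(profiles, function(p) p$oe_unmeth)
  n <- length(profiles)
  sem <- function(m) {
    if (n == 1L) {
      rep(0, nrow(ref))
    } else {
      apply(m, 1L, sd) / sqrt(n)
    }
  }
  out <- ref %>%
    mutate(
      oe_meth = rowMeans(m_meth),
      oe_unmeth = rowMeans(m_unmeth),
      sem_meth = sem(m_meth),
      sem_unmeth = sem(m_unmeth)
    )
  class(out) <- c("oe_profile", class(out))
  out
}

#' Most preferred and most disfavored flanking contexts
#'
#' Sorts the 256 contexts of one substrate class by rate constant
#' (deterministically; ties broken lexicographically by context) and reports
#' the top-m and bottom-m subsets together with per-position base occurrence
#' counts within each subset at the -2, -1, +1, +2 positions.
#'
#' @param rates Rate table slice for a single substrate class (tibble with
#'   `context`, `k`; 256 contexts required).
#' @param m Subset size (default 20; `2 * m` must not exceed 256).
#' @return List of class `ranked_contexts`: `top`, `bottom` (context
#'   vectors, rate-sorted), and `base_occurrence`, a tibble of per-subset,
#'   per-position base counts.
#' @export
extreme_flanks <- function(rates, m = 20L) {
  m <- as.integer(m)
  if (dplyr::n_distinct(rates$substrate_class %||% "x") > 1L) {
    abort("`rates` must be a single-class slice")
  }
  if (2L * m > 256L) abort("`2 * m` must be <= 256")
  missing <- setdiff(nncgnn_contexts(), rates$context)
  if (length(missing)) {
    abort(sprintf(
      "missing contexts: %s%s",
      paste(head(missing, 10), collapse = ", "),
      if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10) else ""
    ))
  }
  ranked <- rates %>%
    filter(is.finite(k)) %>%
    arrange(desc(k), context)
  top <- head(ranked$context, m)
  bottom <- tail(ranked$context, m)

  occurrence <- function(ctx, label) {
    tibble(
      subset_ = label,
      position = rep(c(-2L, -1L, 1L, 2L), each = length(ctx)),
      base = c(
        substr(ctx, 1, 1), substr(ctx, 2, 2),
        substr(ctx, 5, 5), substr(ctx, 6, 6)
      )
    ) %>%
      count(subset_, position, base, name = "count")
  }
  occ <- bind_rows(occurrence(top, "top"), occurrence(bottom, "bottom")) %>%
    tidyr::complete(subset_, position,
      base = .BASES,
      fill = list(count = 0L)
    ) %>%
    rename(subset = subset_)

  structure(
    list(top = top, bottom = bottom, m = m, base_occurrence = occ),
    class = "ranked_contexts"
  )
}

#' @export
print.ranked_contexts <- function(x, ...) {
  cat(sprintf(
    "<ranked_contexts> top-%d: %s ...\n              bottom-%d: %s ...\n",
    x$m, paste(head(x$top, 4), collapse = ", "),
    x$m, paste(head(x$bottom, 4), collapse = ", ")
  ))
  invisible(x)
}
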