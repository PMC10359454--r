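# Monoexponential reaction-progress fitting.
#
# The methylated fraction of a context at dose d (relative enzyme
# concentration x time, pseudo-first-order) follows
#   y(d) = plateau * (1 - exp(-k * d)),
# and k is estimated per (substrate class, NNCGNN context) by bounded
# weighted least squares with read-count weights and multi-start
# initialization. Fits from different experiments are brought to a common
# scale via the class-average rates and merged into a rate table with SEM.

sse_mono <- function(k, d, y, w, plateau) {
  sum(w * (y - plateau * (1 - exp(-k * d)))^2)
}

fit_k_fixed_plateau <- function(d, y, w, plateau, k_max = 1e4) {
  # closed-form start from the log-linearized points plus fixed multi-starts
  yy <- pmin(y / plateau, 0.999)
  ok <- d > 0 & yy > 0
  starts <- c(0.01, 0.1, 1)
  if (any(ok)) {
    k0 <- mean(-log(1 - yy[ok]) / d[ok])
    if (is.finite(k0) && k0 > 0) starts <- c(k0, starts)
  }
  best <- NULL
  for (k0 in starts) {
    fit <- suppressWarnings(nlminb(
      start = k0,
      objective = sse_mono,
      lower = 0, upper = k_max,
      d = d, y = y, w = w, plateau = plateau
    ))
    if (is.null(best) ||
      fit$objective < best$objective - 1e-12 ||
      (abs(fit$objective - best$objective) <= 1e-12 && fit$par < best$par)) {
      best <- fit
    }
  }
  best
}

new_mono_fit <- function(k, plateau, rss, n_points, status) {
  structure(
    list(k = k, plateau = plateau, rss = rss, n_points = n_points, status = status),
    class = "mono_fit"
  )
}

#' @export
print.mono_fit <- function(x, ...) {
  cat(sprintf(
    "<mono_fit> k = %.4g, plateau = %.3g, rss = %.3g, n = %d, status = %s\n",
    x$k, x$plateau, x$rss, x$n_points, x$status
  ))
  invisible(x)
}

#' Fit a monoexponential reaction progress curve
#'
#' Estimates the first-order rate constant k from (dose, methylated fraction)
#' observations of one context by minimizing the read-count-weighted sum of
#' squares of `y - plateau * (1 - exp(-k * d))`, with k bounded below by 0
#' and multi-start initialization (k0 in 0.01, 0.1, 1 per unit dose plus a
#' log-linearized start); ties are broken by lowest residual, then smallest
#' k.
#'
#' @param obs Tibble with columns `dose`, `fraction` and optionally
#'   `n_reads` (weights; default 1).
#' @param plateau Either a fixed maximal methylated fraction (default 1) or
#'   `"fit"` to estimate plateau and k jointly (used by [fit_experiment()]
#'   for its global-plateau stage).
#' @return A `mono_fit` object with elements `k`, `plateau`, `rss`,
#'   `n_points` and `status` (`"ok"`, `"boundary"` when k hit 0, or
#'   `"insufficient-data"`). [tidy()] and [glance()] methods are available.
#' @export
#' @examples
#' obs <- tibble::tibble(dose = c(1, 5, 10, 20), fraction = 1 - exp(-0.1 * c(1, 5, 10, 20)))
#' fit_monoexponential(obs)
fit_monoexponential <- function(obs, plateau = 1) {
  d <- obs$dose
  y <- obs$fraction
  w <- if ("n_reads" %in% names(obs)) obs$n_reads else rep(1, length(d))
  keep <- is.finite(d) & is.finite(y) & w > 0
  d <- d[keep]
  y <- y[keep]
  w <- w[keep]

  n_pts <- length(d)
  if (length(unique(d)) < 2L || !any(d > 0)) {
    return(new_mono_fit(NA_real_, NA_real_, NA_real_, n_pts, "insufficient-data"))
  }

  fit_plateau <- identical(plateau, "fit")
  if (fit_plateau) {
    obj2 <- function(par) sse_mono(par[1], d, y, w, plateau = par[2])
    best <- NULL
    for (k0 in c(0.01, 0.1, 1)) {
      fit <- suppressWarnings(nlminb(
        start = c(k0, max(max(y), 0.5)),
        objective = obj2,
        lower = c(0, 1e-6), upper = c(1e4, 1)
      ))
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    k <- best$par[1]
    pl <- best$par[2]
    rss <- best$objective
  } else {
    best <- fit_k_fixed_plateau(d, y, w, plateau)
    k <- best$par
    pl <- plateau
    rss <- best$objective
  }
  status <- if (k <= 0 || all(y == 0)) "boundary" else "ok"
  if (k <= 0) k <- 0
  new_mono_fit(k, pl, rss, n_pts, status)
}

#' Fit all contexts of one experiment
#'
#' Turns a per-(class, dose, context) count table into per-context rate
#' constants. Dose points with fewer than `min_reads` total reads for a
#' context are excluded from that context's fit; contexts left with fewer
#' than two distinct doses are flagged `"insufficient-data"`. With
#' `plateau = "fit"` a single global plateau per substrate class is
#' estimated first from the class-pooled progress curve (accounting for a
#' non-convertible or inactive substrate fraction) and then fixed for the
#' per-context fits.
#'
#' @param counts Context count tibble ([tabulate_contexts()] output).
#' @param plateau Fixed plateau (default 1) or `"fit"`.
#' @param min_reads Minimum total reads per context per dose (default 50).
#' @return Tibble with `substrate_class`, `context`, `k`, `plateau`, `rss`,
#'   `n_points`, `status`.
#' @export
fit_experiment <- function(counts, plateau = 1, min_reads = 50L) {
  counts <- counts %>%
    mutate(fraction = ifelse(n_total > 0, n_meth / n_total, NA_real_))

  plateau_by_class <- NULL
  if (identical(plateau, "fit")) {
    plateau_by_class <- counts %>%
      group_by(substrate_class, dose) %>%
      summarise(n_meth = sum(n_meth), n_total = sum(n_total), .groups = "drop_last") %>%
      summarise(
        plateau = {
          obs <- tibble(
            dose = dose, fraction = n_meth / n_total, n_reads = n_total
          )
          fit_monoexponential(obs, plateau = "fit")$plateau
        },
        .groups = "drop"
      )
  }

  fits <- counts %>%
    filter(n_total >= min_reads) %>%
    group_by(substrate_class, context) %>%
    summarise(
      fit = list(fit_monoexponential(
        tibble(dose = dose, fraction = fraction, n_reads = n_total),
        plateau = if (is.null(plateau_by_class)) {
          plateau
        } else {
          plateau_by_class$plateau[
            match(dplyr::cur_group()$substrate_class, plateau_by_class$substrate_class)
          ]
        }
      )),
      .groups = "drop"
    ) %>%
    mutate(
      k = purrr::map_dbl(fit, "k"),
      plateau = purrr::map_dbl(fit, "plateau"),
      rss = purrr::map_dbl(fit, "rss"),
      n_points = purrr::map_int(fit, "n_points"),
      status = purrr::map_chr(fit, "status")
    ) %>%
    select(-fit)

  dropped <- counts %>%
    distinct(substrate_class, context) %>%
    dplyr::anti_join(fits, by = c("substrate_class", "context"))
  if (nrow(dropped) > 0L) {
    fits <- bind_rows(
      fits,
      mutate(dropped,
        k = NA_real_, plateau = NA_real_, rss = NA_real_,
        n_points = 0L, status = "insufficient-data"
      )
    )
  }
  arrange(fits, substrate_class, context)
}

#' Scale experiments to a common axis and merge into a rate table
#'
#' Different experiments (time-point series at different enzyme
#' concentrations) yield rates on arbitrary relative scales. Each experiment
#' is rescaled to the reference via the class-average rates of the substrate
#' classes it shares with the reference (geometric mean of the per-class
#' factors `mean k in reference / mean k in experiment`), making the merged
#' table invariant to multiplying any single experiment by a positive
#' constant. Scaled per-context rates are then averaged across experiments,
#' with SEM = sample SD / sqrt(n).
#'
#' @param experiments List of per-context fit tibbles ([fit_experiment()]
#'   outputs).
#' @param reference Index (or name) of the reference experiment (default 1).
#' @return Rate table tibble of class `rate_table`: `substrate_class`,
#'   `context`, `k`, `sem`, `n_experiments`; all 256 contexts are present
#'   per class (NA where no experiment yielded a usable fit).
#' @export
scale_and_merge <- function(experiments, reference = 1L) {
  stopifnot(length(experiments) >= 1L)
  ref <- experiments[[reference]]
  class_means <- function(x) {
    x %>%
      filter(status == "ok", is.finite(k)) %>%
      group_by(substrate_class) %>%
      summarise(mean_k = mean(k), .groups = "drop")
  }
  ref_means <- class_means(ref)

  scaled <- purrr::imap(experiments, function(x, i) {
    m <- class_means(x)
    shared <- inner_join(ref_means, m,
      by = "substrate_class",
      suffix = c("_ref", "_exp")
    )
    if (nrow(shared) == 0L) {
      abort(sprintf("experiment %s shares no substrate class with the reference", i))
    }
    if (any(shared$mean_k_exp == 0) || any(shared$mean_k_ref == 0)) {
      abort("zero class-mean rate; cannot compute a scale factor")
    }
    f <- exp(mean(log(shared$mean_k_ref / shared$mean_k_exp)))
    x %>%
      filter(status %in% c("ok", "boundary")) %>%
      mutate(k = k * f)
  })

  merged <- bind_rows(scaled) %>%
    group_by(substrate_class, context) %>%
    summarise(
      sem = ifelse(dplyr::n() > 1, sd(k) / sqrt(dplyr::n()), 0),
      n_experiments = dplyr::n(),
      k = mean(k),
      .groups = "drop"
    ) %>%
    select(substrate_class, context, k, sem, n_experiments)

  grid <- tidyr::expand_grid(
    substrate_class = sort(unique(merged$substrate_class)),
    context = nncgnn_contexts()
  )
  out <- left_join(grid, merged, by = c("substrate_class", "context")) %>%
    mutate(n_experiments = tidyr::replace_na(n_experiments, 0L)) %>%
    arrange(substrate_class, context)
  class(out) <- c("rate_table", class(out))
  out
}
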