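# End-to-end simulation of one deep-enzymology experiment: randomized pools
# for each substrate class, competitive methylation kinetics over a dose
# series, hairpin bisulfite read-out, reconstruction and per-context
# tabulation.

geometric_mean_rate <- function(model, substrate_class) {
  k <- model$rates$k[model$rates$substrate_class == substrate_class]
  k <- k[k > 0]
  exp(mean(log(k)))
}

#' Default dose schedule for a substrate class
#'
#' Four doses placed so that `k * dose` spans roughly 0.25 to 5.6 at the
#' class's geometric-mean rate, sampling the reaction progress curve from
#' early turnover to near saturation. Scaling by the class mean emulates the
#' experimental practice of probing slow substrate classes with higher
#' enzyme concentrations or longer incubation times.
#'
#' @param model A [rate_model()].
#' @param substrate_class Class whose schedule to compute.
#' @param multipliers Dose multipliers at the class geometric-mean rate.
#' @return Numeric dose vector.
#' @export
default_dose_schedule <- function(model, substrate_class,
                                  multipliers = c(0.25, 0.7, 2, 5.6)) {
  multipliers / geometric_mean_rate(model, substrate_class)
}

#' Simulate one full deep-enzymology experiment
#'
#' For every substrate class and dose, generates a randomized single-CpG
#' pool, simulates methylation kinetics under the ground-truth model, emits
#' hairpin bisulfite read pairs, reconstructs and calls them, and tabulates
#' per-context counts. Work proceeds in per-(class, dose) chunks so memory
#' stays flat at large read counts.
#'
#' @param model A [rate_model()].
#' @param n_per_dose Molecules per class per dose (default 10000).
#' @param classes Substrate classes to include.
#' @param doses Named list of per-class dose vectors; defaults to
#'   [default_dose_schedule()] per class.
#' @param conversion,error_rate Read-out parameters (see [emit_reads()]).
#' @param seed Integer seed for the whole experiment.
#' @param keep `"counts"` (default) or `"records"` to also return the
#'   per-molecule call records (memory-heavy at scale).
#' @param specs Optional named list of [substrate_spec()] overrides.
#' @return List with `counts` (context count tibble), `records` (tibble or
#'   `NULL`), `truth` (per-class/context true rates joined from the model)
#'   and `qc` (aggregated read-processing counters).
#' @export
simulate_experiment <- function(model, n_per_dose = 10000L,
                                classes = c("HM", "OH", "UM"),
                                doses = NULL,
                                conversion = 1, error_rate = 0,
                                seed = 1L,
                                keep = c("counts", "records"),
                                specs = NULL) {
  keep <- arg_match(keep)
  withr::local_seed(seed)
  if (is.null(doses)) {
    doses <- setNames(
      lapply(classes, function(cl) default_dose_schedule(model, cl)),
      classes
    )
  }
  if (is.null(specs)) {
    specs <- setNames(lapply(classes, substrate_spec), classes)
  }

  counts <- list()
  records <- list()
  qc_total <- NULL
  for (cl in classes) {
    for (d in doses[[cl]]) {
      pool <- generate_pool(specs[[cl]], n_per_dose)
      pool <- simulate_kinetics(pool, model, dose = d)
      reads <- emit_reads(pool, conversion = conversion, error_rate = error_rate)
      recs <- process_read_pairs(reads, specs[cl])
      qc <- attr(recs, "qc")
      qc_total <- if (is.null(qc_total)) qc else purrr::map2(qc_total, qc, `+`)
      counts[[length(counts) + 1L]] <- tabulate_contexts(recs)
      if (keep == "records") records[[length(records) + 1L]] <- recs
    }
  }
  counts <- bind_rows(counts) %>%
    group_by(substrate_class, dose, context) %>%
    summarise(n_meth = sum(n_meth), n_total = sum(n_total), .groups = "drop")

  list(
    counts = counts,
    records = if (keep == "records") bind_rows(records) else NULL,
    truth = filter(model$rates, substrate_class %in% classes),
    qc = qc_total
  )
}
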