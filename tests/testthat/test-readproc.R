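test_that("the strand reconstruction rule table is applied per position", {
  # C-free molecule: reads pass through unchanged
  r <- reconstruct_hairpin(tibble::tibble(read1 = "TGT", read2 = "ACA"))
  expect_equal(r$original, "TGT")
  expect_equal(r$n_ambiguous, 0L)

  # upper C retained (protected), lower C of the CpG also protected
  r <- reconstruct_hairpin(tibble::tibble(read1 = "CGA", read2 = "TCG"))
  expect_equal(r$original, "CGA")

  # converted upper C: T over lower G reads as original C
  r <- reconstruct_hairpin(tibble::tibble(read1 = "TGA", read2 = "TCG"))
  expect_equal(r$original, "CGA")

  # converted lower C: G over T
  r <- reconstruct_hairpin(tibble::tibble(read1 = "CGA", read2 = "TTG"))
  expect_equal(r$original, "CGA")

  # contradiction flags the position ambiguous
  r <- reconstruct_hairpin(tibble::tibble(read1 = "CAA", read2 = "TTA"))
  expect_equal(substr(r$original, 1, 1), "N")
  expect_gte(r$n_ambiguous, 1L)

  # length-mismatched pairs are discarded and counted
  mixed <- tibble::tibble(read1 = c("TGT", "TGTT"), read2 = c("ACA", "ACA"))
  r <- reconstruct_hairpin(mixed)
  expect_equal(nrow(r), 1L)
  expect_equal(attr(r, "n_discarded"), 1L)
})

test_that("round trip through emission and reconstruction is exact", {
  spec <- substrate_spec("HM")
  model <- example_rate_model()
  pool <- generate_pool(spec, 2000, seed = 31)
  pool <- simulate_kinetics(pool, model, dose = 1, seed = 32)
  reads <- emit_reads(pool, conversion = 1, error_rate = 0, seed = 33)
  recon <- reconstruct_hairpin(reads)

  expect_equal(recon$original, pool$sequence)
  recs <- call_cpg(recon, spec$cpg_pos, spec$flank_len)
  expect_equal(
    recs$call_upper == "methylated",
    pool$upper_state == "5mC"
  )
  expect_true(all(recs$call_lower == "methylated")) # HM lower strand is 5mC
  expect_equal(recs$nncgnn, pool$context)
})

test_that("methylation calls cover both strands and flag ambiguity", {
  # UM molecule, both strands converted -> (unmethylated, unmethylated)
  spec <- tiny_spec("UM")
  pool <- generate_pool(spec, 50, seed = 41)
  recs <- call_cpg(
    reconstruct_hairpin(emit_reads(pool, seed = 42)),
    spec$cpg_pos, spec$flank_len
  )
  expect_true(all(recs$call_upper == "unmethylated"))
  expect_true(all(recs$call_lower == "unmethylated"))

  # protected upper + converted lower -> (methylated, unmethylated)
  pool$upper_state <- "5mC"
  recs <- call_cpg(
    reconstruct_hairpin(emit_reads(pool, seed = 43)),
    spec$cpg_pos, spec$flank_len
  )
  expect_true(all(recs$call_upper == "methylated"))
  expect_true(all(recs$call_lower == "unmethylated"))

  # an N inside the NNCGNN window marks the record ambiguous
  reads <- emit_reads(pool[1, ], seed = 44)
  substr(reads$read1, spec$cpg_pos - 2, spec$cpg_pos - 2) <- "N"
  recs <- call_cpg(reconstruct_hairpin(reads), spec$cpg_pos, spec$flank_len)
  expect_equal(recs$call_upper, "ambiguous")
})

test_that("context tabulation follows the strand-counting policy", {
  recs <- make_records(
    nncgnn = rep("AACGTT", 10),
    call_upper = rep(c("methylated", "unmethylated"), c(4, 6))
  )
  tab <- tabulate_contexts(recs)
  expect_equal(tab$n_meth, 4L)
  expect_equal(tab$n_total, 10L)

  # UM lower-strand event lands on the reverse-complement context
  um <- make_records(
    nncgnn = "GACGTA",
    call_upper = "unmethylated",
    call_lower = "methylated",
    substrate_class = "UM"
  )
  tab <- tabulate_contexts(um)
  expect_setequal(tab$context, c("GACGTA", "TACGTC"))
  expect_equal(tab$n_meth[tab$context == "TACGTC"], 1L)
  expect_equal(tab$n_meth[tab$context == "GACGTA"], 0L)

  # conservation: totals = unambiguous records (x2 for UM), any row order
  mixed <- dplyr::bind_rows(
    make_records(rep("TTCGAA", 7), rep("methylated", 7), substrate_class = "HM"),
    make_records(rep("GACGTA", 5), rep("unmethylated", 5),
      call_lower = "methylated", substrate_class = "UM"
    ),
    make_records("AACGAA", "ambiguous", substrate_class = "HM")
  )
  tab <- tabulate_contexts(mixed)
  expect_equal(sum(tab$n_total), 7L + 2L * 5L)
  shuffled <- mixed[sample(nrow(mixed)), ]
  expect_equal(tabulate_contexts(shuffled), tab)

  # per-molecule policy counts each UM molecule once
  tab_mol <- tabulate_contexts(mixed, um_policy = "per_molecule")
  expect_equal(sum(tab_mol$n_total), 7L + 5L)
  expect_equal(tab_mol$n_meth[tab_mol$context == "GACGTA"], 5L)
})

test_that("demultiplexing assigns classes by barcode and keeps the rest", {
  specs <- lapply(c("HM", "OH", "UM"), substrate_spec)
  pools <- lapply(specs, generate_pool, n = 30, seed = 51)
  reads <- dplyr::bind_rows(lapply(pools, emit_reads, seed = 52))
  reads$substrate_class <- NULL
  demuxed <- demultiplex_reads(reads, specs)
  expect_equal(unname(table(demuxed$substrate_class)[c("HM", "OH", "UM")]),
    rep(30L, 3),
    ignore_attr = TRUE
  )

  # a corrupted barcode goes to the unassigned bucket (and survives with
  # 1-mismatch tolerance)
  broken <- reads
  substr(broken$read1[1], 1, 1) <- "A"
  expect_equal(demultiplex_reads(broken, specs)$substrate_class[1], "unassigned")
  expect_false(
    demultiplex_reads(broken, specs, max_mismatch = 1)$substrate_class[1] == "unassigned"
  )
})

test_that("background estimation from no-enzyme controls", {
  clean <- tibble::tibble(
    substrate_class = "HM", dose = 0, context = "AACGAA",
    n_meth = 0L, n_total = 10000L
  )
  expect_equal(estimate_background(clean)$background, 0)

  some <- dplyr::mutate(clean, n_meth = 50L)
  expect_equal(estimate_background(some)$background, 0.005)

  empty <- dplyr::mutate(clean, n_total = 0L, n_meth = 0L)
  expect_true(is.na(estimate_background(empty)$background))

  # simulated incomplete conversion: apparent background ~ 1 - conversion
  spec <- substrate_spec("UM")
  pool <- generate_pool(spec, 10000, seed = 61) # no enzyme: zero dose
  pool$dose <- 0
  recs <- call_cpg(
    reconstruct_hairpin(emit_reads(pool, conversion = 0.995, seed = 62)),
    spec$cpg_pos, spec$flank_len
  )
  bg <- estimate_background(tabulate_contexts(recs))$background
  se <- sqrt(0.005 * 0.995 / 20000)
  expect_lt(abs(bg - 0.005), 3 * se)
})

test_that("ambiguous-call fraction grows with the sequencing error rate", {
  spec <- substrate_spec("HM")
  pool <- generate_pool(spec, 3000, seed = 71)
  frac_ambiguous <- vapply(c(0, 0.01, 0.05, 0.15), function(e) {
    recs <- call_cpg(
      reconstruct_hairpin(emit_reads(pool, error_rate = e, seed = 72)),
      spec$cpg_pos, spec$flank_len
    )
    mean(recs$call_upper == "ambiguous")
  }, numeric(1))
  expect_true(all(diff(frac_ambiguous) > 0))
  expect_equal(frac_ambiguous[1], 0)
})

test_that("the full read-processing pipeline reports QC counters", {
  specs <- lapply(c("HM", "UM"), substrate_spec)
  pools <- lapply(specs, function(s) {
    simulate_kinetics(
      generate_pool(s, 200, seed = 81),
      flat_model(), 1,
      seed = 82
    )
  })
  reads <- dplyr::bind_rows(lapply(pools, emit_reads, seed = 83))
  reads$substrate_class <- NULL
  # one read of the wrong size
  reads$read1[5] <- paste0(reads$read1[5], "AAAAAA")
  recs <- process_read_pairs(reads, specs)
  qc <- attr(recs, "qc")
  expect_equal(qc$reads_in, 400L)
  expect_equal(qc$discarded_length, 1L)
  expect_equal(nrow(recs), 399L)
})
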