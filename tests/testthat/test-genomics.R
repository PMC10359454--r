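test_that("genomic profiles apply the coverage filter and context averaging", {
  genome <- c(chr1 = "TTAACGTTTTGACGTATTTTAACGTTAAGG")
  cov <- tibble::tibble(
    chrom = "chr1",
    start = c(5L, 13L, 23L),
    end = start,
    meth_pct = NA_real_,
    count_meth = c(5L, 3L, 2L),
    count_unmeth = c(5L, 7L, 2L)
  )
  prof <- genomic_profile(cov, genome, min_coverage = 4)
  # site at 22 has coverage 4 -> excluded under "keep > 4"
  expect_equal(prof$n_sites[prof$context == "AACGTT"], 1L)
  expect_equal(prof$mean_meth[prof$context == "AACGTT"], 0.5)
  expect_equal(prof$mean_meth[prof$context == "GACGTA"], 0.3)
  expect_true(all(is.na(prof$mean_meth[!prof$context %in% c("AACGTT", "GACGTA")])))

  # a non-CpG site is excluded and counted
  bad <- dplyr::mutate(cov, start = c(5L, 14L, 23L), end = start)
  prof_bad <- genomic_profile(bad, genome, min_coverage = 4)
  expect_gte(attr(prof_bad, "n_excluded"), 1L)

  expect_error(
    genomic_profile(dplyr::mutate(cov, chrom = "chrX"), genome),
    "missing from genome"
  )
})

test_that("uniform methylation gives a flat profile with o/e 1", {
  spec <- synthetic_genome_spec(n_chroms = 1, chrom_len = 40000, coverage_mean = 60)
  sim <- simulate_genomic_table(spec, seed = 131)
  prof <- genomic_profile(sim$coverage, sim$genome, min_coverage = 4)
  seen <- dplyr::filter(prof, n_sites > 0)
  expect_gt(nrow(seen), 200)
  expect_true(all(abs(seen$mean_meth - 0.5) < 0.12))
  expect_equal(mean(seen$oe), 1, tolerance = 0.02)
})

test_that("profiles are invariant to row order and sharding", {
  spec <- synthetic_genome_spec(n_chroms = 2, chrom_len = 10000)
  sim <- simulate_genomic_table(spec, seed = 132)
  prof <- genomic_profile(sim$coverage, sim$genome)

  shuffled <- sim$coverage[sample(nrow(sim$coverage)), ]
  prof_shuffled <- genomic_profile(shuffled, sim$genome)
  expect_equal(as.data.frame(prof_shuffled), as.data.frame(prof))

  # split into shards, profile jointly via recombination
  half <- nrow(sim$coverage) %/% 2
  shards <- dplyr::bind_rows(
    sim$coverage[seq_len(half), ],
    sim$coverage[(half + 1):nrow(sim$coverage), ]
  )
  expect_equal(
    as.data.frame(genomic_profile(shards, sim$genome)),
    as.data.frame(prof)
  )
})

test_that("a context-effect vector is recovered from synthetic WGBS data", {
  model <- example_rate_model()
  um <- dplyr::filter(model$rates, substrate_class == "UM")
  effect <- setNames(
    0.1 + 0.8 * (um$k - min(um$k)) / diff(range(um$k)),
    um$context
  )
  spec <- synthetic_genome_spec(
    n_chroms = 2, chrom_len = 100000,
    context_effect = effect, coverage_mean = 100
  )
  sim <- simulate_genomic_table(spec, seed = 133)
  prof <- genomic_profile(sim$coverage, sim$genome, min_coverage = 4)
  r <- correlate(prof, tibble::tibble(context = names(effect), value = unname(effect)))
  expect_gt(r, 0.95)
})

test_that("pearson correlation behaves under affine maps and degenerate input", {
  a <- setNames(as.numeric(1:256), nncgnn_contexts())
  expect_equal(correlate(a, a), 1)
  expect_equal(correlate(a, -a + 7), -1)
  b <- setNames(rep(c(2, 4, 6, 8), 64), nncgnn_contexts())
  expect_equal(correlate(b / 2, b), 1)
  const <- setNames(rep(1, 256), nncgnn_contexts())
  expect_warning(r <- correlate(a, const), "variance")
  expect_true(is.na(r))
})

test_that("the randomization Z-test is calibrated and reproducible", {
  vals <- withr::with_seed(134, runif(256))
  genomic <- setNames(vals, nncgnn_contexts())

  # self-correlation: r = 1, null near 0, p extremely small
  self <- randomization_pvalue(genomic, genomic, n_shuffles = 20, seed = 7)
  expect_equal(self$r_observed, 1)
  expect_lt(abs(self$null_mean), 0.1)
  expect_lt(self$p, 1e-6)

  # fixed seed reproduces the test exactly
  again <- randomization_pvalue(genomic, genomic, n_shuffles = 20, seed = 7)
  expect_identical(tidy(self), tidy(again))

  # degenerate shuffle count is computed but flagged
  expect_message(
    low <- randomization_pvalue(genomic, genomic, n_shuffles = 2, seed = 8),
    "low-confidence"
  )
  expect_true(low$low_confidence)
  expect_error(randomization_pvalue(genomic, genomic, n_shuffles = 1), "n_shuffles")
})

test_that("independent profiles give non-concentrated p-values", {
  genomic <- setNames(withr::with_seed(135, runif(256)), nncgnn_contexts())
  ps <- vapply(1:200, function(i) {
    pref <- setNames(withr::with_seed(1000 + i, runif(256)), nncgnn_contexts())
    randomization_pvalue(genomic, pref, n_shuffles = 20, seed = i)$p
  }, numeric(1))
  frac_sig <- mean(ps < 0.05)
  expect_gte(frac_sig, 0.01)
  expect_lte(frac_sig, 0.12)
})

test_that("correlation difference tests detect the better-matching profile", {
  model <- example_rate_model()
  um <- dplyr::filter(model$rates, substrate_class == "UM")
  hm <- dplyr::filter(model$rates, substrate_class == "HM")

  # genomic profile built from the UM preference vector
  effect <- setNames(
    0.1 + 0.8 * (um$k - min(um$k)) / diff(range(um$k)),
    um$context
  )
  spec <- synthetic_genome_spec(
    n_chroms = 2, chrom_len = 60000,
    context_effect = effect, coverage_mean = 100
  )
  sim <- simulate_genomic_table(spec, seed = 136)
  prof <- genomic_profile(sim$coverage, sim$genome)

  dt <- correlation_difference_test(prof, um, hm, n_shuffles = 20, seed = 9)
  expect_gt(dt$r_observed, 0)
  expect_lt(dt$p, 0.05)

  # identical preference profiles: delta r = 0, p near 1/2
  same <- correlation_difference_test(prof, um, um, n_shuffles = 50, seed = 10)
  expect_equal(same$r_observed, 0)
  expect_gt(same$p, 0.2)
  expect_lt(same$p, 0.8)

  # swapping the profiles negates the observed difference
  swapped <- correlation_difference_test(prof, hm, um, n_shuffles = 20, seed = 9)
  expect_equal(swapped$r_observed, -dt$r_observed)
})
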