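test_that("generated pools respect the substrate design", {
  spec <- substrate_spec("UM")
  pool <- generate_pool(spec, 1000, seed = 1)

  expect_equal(nrow(pool), 1000)
  expect_true(all(pool$lower_state == "C"))
  expect_true(all(pool$upper_state == "C"))
  expect_true(all(nchar(pool$sequence) == 67))
  expect_true(all(substr(pool$sequence, spec$cpg_pos, spec$cpg_pos + 1) == "CG"))
  expect_true(all(substr(pool$context, 3, 4) == "CG"))

  # every CG lies inside the NNCGNN window (no uncontrolled target sites)
  starts <- gregexpr("CG", pool$sequence, fixed = TRUE)
  allowed <- spec$cpg_pos + c(-2L, 0L, 2L)
  expect_true(all(vapply(starts, function(s) all(s %in% allowed), logical(1))))

  hm <- generate_pool(substrate_spec("HM"), 1, seed = 2)
  expect_equal(hm$lower_state, "5mC")
  expect_equal(hm$upper_state, "C")
  oh <- generate_pool(substrate_spec("OH"), 1, seed = 2)
  expect_equal(oh$lower_state, "5hmC")

  # determinism
  expect_identical(
    generate_pool(spec, 50, seed = 7),
    generate_pool(spec, 50, seed = 7)
  )

  expect_error(substrate_spec("UM", flank_len = 1), "flank_len")
  expect_error(substrate_spec("UM", barcode = "ACGT"), "CpG")
  expect_error(generate_pool(spec, 0), "positive")
})

test_that("all 256 contexts are reachable, including CG-containing ones", {
  pool <- generate_pool(substrate_spec("HM"), 60000, seed = 3)
  expect_length(setdiff(nncgnn_contexts(), unique(pool$context)), 0)
  expect_gt(sum(pool$context == "CGCGCG"), 0)
})

test_that("flank base composition matches a brute-force rejection oracle", {
  spec <- substrate_spec("UM", flank_len = 3, total_len = 30)
  pool <- generate_pool(spec, 30000, seed = 11)
  windows <- substr(pool$sequence, spec$cpg_pos - 3, spec$cpg_pos + 4)

  oracle <- brute_force_windows(flank_len = 3, n = 30000, seed = 12)
  pos <- c(1:3, 6:8) # flank positions of the 8-mer window
  f_obs <- per_position_base_freq(windows, pos)
  f_oracle <- per_position_base_freq(oracle, pos)

  expect_lt(max(abs(f_obs - f_oracle)), 0.015)
  # conditioning depresses C/G below 0.25 at positions adjacent to the core
  expect_lt(f_obs["G", 3], 0.25)
  expect_gt(f_obs["A", 1], 0.20)
})

test_that("kinetics follow the monoexponential law", {
  spec <- substrate_spec("HM")
  model <- flat_model(k_hm = log(2))
  pool <- generate_pool(spec, 10000, seed = 4)

  none <- simulate_kinetics(pool, model, dose = 0, seed = 5)
  expect_true(all(none$upper_state == "C"))

  # k * dose = ln 2 with plateau 1 -> expected methylated fraction 0.5
  half <- simulate_kinetics(pool, model, dose = 1, seed = 6)
  frac <- mean(half$upper_state == "5mC")
  se <- sqrt(0.25 / nrow(pool))
  expect_lt(abs(frac - 0.5), 3 * se)

  # a zero-rate context never reacts
  zero_model <- flat_model(k_hm = 0)
  dead <- simulate_kinetics(pool, zero_model, dose = 100, seed = 7)
  expect_true(all(dead$upper_state == "C"))

  # unknown context errors by name
  bad <- rate_model(
    tibble::tibble(substrate_class = "HM", context = "AACGAA", k = 1)
  )
  expect_error(simulate_kinetics(pool, bad, dose = 1), "context")
})

test_that("UM molecules react on both strands with strand-oriented rates", {
  spec <- substrate_spec("UM")
  ctx <- nncgnn_contexts()
  # saturating rate: both strands of every UM molecule must react
  model <- rate_model(
    tibble::tibble(substrate_class = "UM", context = ctx, k = 1000)
  )
  pool <- generate_pool(spec, 500, seed = 8)
  done <- simulate_kinetics(pool, model, dose = 1, seed = 9)
  expect_true(all(done$upper_state == "5mC"))
  expect_true(all(done$lower_state == "5mC"))

  # HM molecules never change their lower strand
  hm <- generate_pool(substrate_spec("HM"), 200, seed = 8)
  hm <- simulate_kinetics(hm, flat_model(k_hm = 1000), dose = 1, seed = 10)
  expect_true(all(hm$lower_state == "5mC"))
  expect_true(all(hm$upper_state == "5mC"))
})

test_that("read emission applies bisulfite chemistry", {
  spec <- substrate_spec("UM", flank_len = 2, total_len = 30)
  pool <- generate_pool(spec, 200, seed = 13)
  reads <- emit_reads(pool, conversion = 1, error_rate = 0, seed = 14)
  expect_equal(nrow(reads), nrow(pool)) # conservation

  w <- nchar(reads$read1[1])
  # unmethylated upper CpG C reads T; the paired lower G stays G in read2
  expect_true(all(substr(reads$read1, spec$cpg_pos, spec$cpg_pos) == "T"))
  expect_true(all(
    substr(reads$read2, w - spec$cpg_pos + 1, w - spec$cpg_pos + 1) == "G"
  ))
  # unmethylated lower CpG C also converts: aligned base under the upper G is T
  expect_true(all(substr(reads$read2, w - spec$cpg_pos, w - spec$cpg_pos) == "T"))

  # methylated upper CpG retains C; protected lower strand (HM/OH) retains C
  hm_pool <- generate_pool(substrate_spec("HM", flank_len = 2, total_len = 30), 100, seed = 15)
  hm_pool$upper_state <- "5mC"
  hm_reads <- emit_reads(hm_pool, conversion = 1, error_rate = 0, seed = 16)
  expect_true(all(substr(hm_reads$read1, spec$cpg_pos, spec$cpg_pos) == "C"))
  expect_true(all(substr(hm_reads$read2, w - spec$cpg_pos, w - spec$cpg_pos) == "C"))

  # partial conversion: non-converted fraction ~ 1 - conversion
  big <- generate_pool(spec, 5000, seed = 17)
  partial <- emit_reads(big, conversion = 0.99, error_rate = 0, seed = 18)
  n_c <- sum(substr(partial$read1, spec$cpg_pos, spec$cpg_pos) == "C")
  se <- sqrt(0.01 * 0.99 * 5000)
  expect_lt(abs(n_c - 50), 3 * se)

  expect_error(emit_reads(pool, conversion = 1.5), "conversion")
})

test_that("identical seeds give byte-identical FASTQ output", {
  pool <- generate_pool(substrate_spec("HM"), 100, seed = 20)
  pool <- simulate_kinetics(pool, flat_model(), dose = 1, seed = 21)
  d <- withr::local_tempdir()
  p1 <- file.path(d, c("a_R1.fq", "a_R2.fq"))
  p2 <- file.path(d, c("b_R1.fq", "b_R2.fq"))
  write_fastq_pairs(emit_reads(pool, seed = 22), p1[1], p1[2])
  write_fastq_pairs(emit_reads(pool, seed = 22), p2[1], p2[2])
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  expect_identical(readLines(p1[2]), readLines(p2[2]))

  back <- read_fastq_pairs(p1[1], p1[2])
  expect_equal(back$substrate_class, rep("HM", 100))
  expect_equal(back$dose, rep(1, 100))
})

test_that("long substrates satisfy the site pattern constraints", {
  sub <- generate_long_substrate(seed = 1)
  expect_equal(nchar(sub$sequence), 349)
  expect_equal(nrow(sub$sites), 44)
  expect_equal(sum(sub$sites$lower_state == "5mC"), 18)
  expect_equal(sum(sub$sites$lower_state == "C"), 26)
  expect_true(all(
    substr(sub$sequence, sub$sites$position, sub$sites$position + 1) == "CG"
  ))
  # the only CGs in the molecule are the designed sites
  starts <- unlist(gregexpr("CG", sub$sequence, fixed = TRUE))
  expect_setequal(starts, sub$sites$position)
  # hemimethylated sites are exactly the CCGG/GCGC ones
  expect_setequal(
    sub$sites$four_mer[sub$sites$lower_state == "5mC"],
    intersect(unique(sub$sites$four_mer), c("CCGG", "GCGC"))
  )

  all_um <- generate_long_substrate(seed = 2, pattern_rule = function(x) FALSE)
  expect_true(all(all_um$sites$lower_state == "C"))
  all_hm <- generate_long_substrate(seed = 3, pattern_rule = function(x) TRUE)
  expect_true(all(all_hm$sites$lower_state == "5mC"))
})

test_that("synthetic genome coverage tables reflect context effects", {
  spec <- synthetic_genome_spec(
    n_chroms = 1, chrom_len = 30000,
    coverage_mean = 50
  )
  sim <- simulate_genomic_table(spec, seed = 5)
  expect_true(all(c("chrom", "start", "end", "count_meth", "count_unmeth") %in%
    names(sim$coverage)))
  # all sites really are CpGs in the genome
  g <- sim$genome[[1]]
  expect_true(all(
    substr(g, sim$coverage$start, sim$coverage$start + 1) == "CG"
  ))
  total <- sum(sim$coverage$count_meth + sim$coverage$count_unmeth)
  frac <- sum(sim$coverage$count_meth) / total
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / total))

  zero <- synthetic_genome_spec(
    n_chroms = 1, chrom_len = 5000,
    context_effect = setNames(rep(0, 256), nncgnn_contexts())
  )
  sim0 <- simulate_genomic_table(zero, seed = 6)
  expect_true(all(sim0$coverage$count_meth == 0))
})
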