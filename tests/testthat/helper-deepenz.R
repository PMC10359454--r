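# Shared fixtures and independent oracles for the test suite.

# small substrate: 2-nt flanks so windows are the bare NNCGNN context
tiny_spec <- function(class = "UM") {
  substrate_spec(class, flank_len = 2, total_len = 30)
}

# rate model with one constant rate per class (no flanking preference)
flat_model <- function(k_hm = 1, k_oh = 0.5, k_um = 0.25, plateau = 1) {
  ctx <- nncgnn_contexts()
  rate_model(
    dplyr::bind_rows(
      tibble::tibble(substrate_class = "HM", context = ctx, k = k_hm),
      tibble::tibble(substrate_class = "OH", context = ctx, k = k_oh),
      tibble::tibble(substrate_class = "UM", context = ctx, k = k_um)
    ),
    plateau = plateau
  )
}

# pool -> kinetics -> reads -> reconstruction -> call records, one class
simulate_records <- function(spec, model, dose, n, seed,
                             conversion = 1, error_rate = 0) {
  pool <- generate_pool(spec, n, seed = seed)
  pool <- simulate_kinetics(pool, model, dose = dose, seed = seed + 1000L)
  reads <- emit_reads(pool,
    conversion = conversion, error_rate = error_rate,
    seed = seed + 2000L
  )
  recon <- reconstruct_hairpin(reads)
  call_cpg(recon, spec$cpg_pos, spec$flank_len)
}

# hand-built call records (readproc/profiles unit tests)
make_records <- function(nncgnn, call_upper, call_lower = "unmethylated",
                         substrate_class = "HM", dose = 1) {
  tibble::tibble(
    substrate_class = substrate_class,
    dose = dose,
    original = nncgnn,
    flank_window = nncgnn,
    nncgnn = nncgnn,
    call_upper = call_upper,
    call_lower = call_lower
  )
}

# independent oracle: exhaustive grid search for the weighted least-squares k
grid_search_k <- function(d, y, w, plateau = 1,
                          k_range = c(1e-4, 10), n_grid = 4000) {
  sse <- function(k) sum(w * (y - plateau * (1 - exp(-k * d)))^2)
  grid <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_grid))
  k0 <- grid[which.min(vapply(grid, sse, numeric(1)))]
  # local refinement around the best grid point, still derivative-free
  fine <- seq(k0 * 0.98, k0 * 1.02, length.out = 2001)
  fine[which.min(vapply(fine, sse, numeric(1)))]
}

# independent oracle: brute-force rejection sampler for randomized windows.
# Samples windows uniformly and keeps those whose CG dinucleotides all lie
# inside the NNCGNN context, using plain string matching.
brute_force_windows <- function(flank_len, n, seed) {
  withr::with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      left <- vapply(
        seq_len(2L * n),
        function(i) paste(sample(c("A", "C", "G", "T"), flank_len, TRUE), collapse = ""),
        character(1)
      )
      right <- vapply(
        seq_len(2L * n),
        function(i) paste(sample(c("A", "C", "G", "T"), flank_len, TRUE), collapse = ""),
        character(1)
      )
      win <- paste0(left, "CG", right)
      starts <- gregexpr("CG", win, fixed = TRUE)
      allowed <- c(flank_len - 1L, flank_len + 1L, flank_len + 3L)
      ok <- vapply(starts, function(s) all(s %in% allowed), logical(1))
      out <- c(out, win[ok])
    }
    out[seq_len(n)]
  })
}

per_position_base_freq <- function(windows, positions) {
  sapply(positions, function(p) {
    b <- substr(windows, p, p)
    table(factor(b, levels = c("A", "C", "G", "T"))) / length(b)
  })
}
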