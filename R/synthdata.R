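# Synthetic deep-enzymology data with known kinetic ground truth.
#
# The generator emulates the experimental design: 67-bp double-stranded
# substrates carrying a single CpG in 10 nt of randomized flanking sequence on
# either side, present as hemimethylated (HM, lower-strand 5mC),
# hemihydroxymethylated (OH, lower-strand 5hmC) or unmethylated (UM) pools;
# enzymatic methylation following first-order kinetics with
# flanking-context-dependent rate constants; hairpin ligation and bisulfite
# conversion read out as paired sequencing reads.

# C-free filler used for the constant regions framing the randomized window.
# Keeping the fixed parts free of cytosine means bisulfite conversion cannot
# touch them and they can never contribute a CpG.
.PAD_POOL <- "TAGTTAGGATGTTAGAGTAAGGTTAGAATGGATTGAGTAAGTTAGGATTAGATGGTAGATTGAG"

.DEFAULT_BARCODES <- c(HM = "TGTGAT", OH = "AGATGA", UM = "TTGAGA")

#' Specify a randomized single-CpG substrate
#'
#' Describes one substrate pool of the deep-enzymology experiment: a
#' double-stranded molecule of `total_len` bp with a single central CpG
#' embedded in `flank_len` randomized bases on each side, a class-specific
#' barcode at the 5' end, and C-free constant filler elsewhere.
#'
#' @param substrate_class One of `"HM"` (lower-strand 5mC), `"OH"`
#'   (lower-strand 5hmC) or `"UM"` (both strands unmethylated).
#' @param barcode Short fixed sequence placed at the start of the molecule,
#'   outside the randomized region. Must not contain a CpG; the defaults are
#'   C-free so that bisulfite conversion leaves them intact.
#' @param flank_len Number of randomized bases on each side of the CpG
#'   (default 10, minimum 2 so that the NNCGNN context is defined).
#' @param total_len Total substrate length in bp (default 67).
#' @return An object of class `substrate_spec`.
#' @export
#' @examples
#' substrate_spec("HM")
substrate_spec <- function(substrate_class = c("HM", "OH", "UM"),
                           barcode = NULL,
                           flank_len = 10L,
                           total_len = 67L) {
  substrate_class <- arg_match(substrate_class)
  if (is.null(barcode)) barcode <- unname(.DEFAULT_BARCODES[substrate_class])
  flank_len <- as.integer(flank_len)
  total_len <- as.integer(total_len)
  if (flank_len < 2L) {
    abort("`flank_len` must be >= 2: the NNCGNN context is undefined otherwise.")
  }
  if (grepl("CG", barcode)) abort("`barcode` must not contain a CpG.")
  if (grepl("[^ACGT]", barcode)) abort("`barcode` must be an A/C/G/T string.")
  bl <- nchar(barcode)
  if (total_len < 2L * flank_len + 2L + bl) {
    abort("`total_len` must be >= 2 * flank_len + 2 + nchar(barcode).")
  }

  pad_total <- total_len - bl - 2L * flank_len - 2L
  pad_left_len <- pad_total %/% 2L
  pad_right_len <- pad_total - pad_left_len
  pad_left <- substr(.PAD_POOL, 1L, pad_left_len)
  # right filler starts with A so a randomized C at the flank end can never
  # pair into an extra CpG across the boundary
  pad_right <- substr(paste0("A", .PAD_POOL), 1L, pad_right_len)

  structure(
    list(
      substrate_class = substrate_class,
      barcode = barcode,
      flank_len = flank_len,
      total_len = total_len,
      pad_left = pad_left,
      pad_right = pad_right,
      cpg_pos = bl + pad_left_len + flank_len + 1L
    ),
    class = "substrate_spec"
  )
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat(sprintf(
    "<substrate_spec> %s: %d bp, barcode %s, %d-nt randomized flanks, CpG C at %d\n",
    x$substrate_class, x$total_len, x$barcode, x$flank_len, x$cpg_pos
  ))
  invisible(x)
}

default_lower_state <- function(substrate_class) {
  c(HM = "5mC", OH = "5hmC", UM = "C")[substrate_class]
}

#' Generate a pool of randomized single-CpG molecules
#'
#' Draws `n` substrate molecules whose flanking bases are i.i.d. uniform over
#' A/C/G/T subject to the constraint that no CpG occurs outside the NNCGNN
#' context window. CpGs formed by the two context bases on either side of
#' the central CpG (contexts such as `CGCGNN` or `NNCGCG`) are genuine
#' measurable contexts and are kept -- excluding them would make 31 of the
#' 256 contexts unobservable -- while molecules whose random flanks create
#' CpGs further out are regenerated by rejection sampling so that the
#' molecule carries no uncontrolled target sites; the rejection rate is
#' recorded in the `rejection_rate` attribute. Conditioning on "no outside
#' CG" slightly depresses the marginal C and G frequencies in the flanks
#' relative to 0.25 (see the methods vignette).
#'
#' @param spec A [substrate_spec()].
#' @param n Number of molecules to generate.
#' @param seed Optional integer seed; given the same seed the pool is
#'   reproduced exactly.
#' @return A tibble with one row per molecule: `molecule_id`,
#'   `substrate_class`, `sequence` (upper strand, pre-conversion),
#'   `cpg_pos` (position of the CpG C), `context` (NNCGNN 6-mer),
#'   `upper_state` (`"C"` until methylation is simulated), `lower_state`
#'   (`"C"`, `"5mC"` or `"5hmC"`), `dose` (`NA` until kinetics are simulated).
#' @export
#' @examples
#' pool <- generate_pool(substrate_spec("UM"), n = 5, seed = 1)
#' pool$context
generate_pool <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "substrate_spec"))
  n <- as.integer(n)
  if (n <= 0L) abort("`n` must be positive.")
  if (!is.null(seed)) withr::local_seed(seed)

  prefix <- paste0(spec$barcode, spec$pad_left)
  fl <- spec$flank_len
  width_rand <- 2L * fl + 2L

  draw_windows <- function(m) {
    # randomized window: left flank + CG + right flank
    win <- matrix(.BYTE_N, nrow = width_rand, ncol = m)
    win[seq_len(fl), ] <- random_base_bytes(fl * m)
    win[fl + 1L, ] <- .BYTE_C
    win[fl + 2L, ] <- .BYTE_G
    win[fl + 2L + seq_len(fl), ] <- random_base_bytes(fl * m)
    win
  }

  # CG dinucleotides are permitted only at these start offsets within the
  # randomized window: the designed CpG itself and the two context slots
  # (N1N2 = CG or N3N4 = CG)
  allowed_starts <- c(fl - 1L, fl + 1L, fl + 3L)
  allowed_starts <- allowed_starts[allowed_starts >= 1L & allowed_starts < width_rand]

  window_ok <- function(win) {
    nr <- nrow(win)
    hits <- (win[-nr, , drop = FALSE] == .BYTE_C) &
      (win[-1L, , drop = FALSE] == .BYTE_G)
    hits[allowed_starts, ] <- FALSE
    colSums(hits) == 0L
  }

  accepted <- matrix(.BYTE_N, nrow = width_rand, ncol = 0L)
  n_rejected <- 0L
  n_left <- n
  iter <- 0L
  while (n_left > 0L) {
    iter <- iter + 1L
    if (iter > 1000L) abort("rejection sampling failed to converge")
    win <- draw_windows(n_left)
    ok <- window_ok(win)
    n_rejected <- n_rejected + sum(!ok)
    accepted <- cbind(accepted, win[, ok, drop = FALSE])
    n_left <- n_left - sum(ok)
  }

  windows <- bytes_to_seq(accepted)
  sequence <- paste0(prefix, windows, spec$pad_right)
  context <- substr(sequence, spec$cpg_pos - 2L, spec$cpg_pos + 3L)

  pool <- tibble(
    molecule_id = paste0(spec$substrate_class, "_", seq_len(n)),
    substrate_class = spec$substrate_class,
    sequence = sequence,
    cpg_pos = spec$cpg_pos,
    context = context,
    upper_state = "C",
    lower_state = unname(default_lower_state(spec$substrate_class)),
    dose = NA_real_
  )
  attr(pool, "rejection_rate") <- n_rejected / (n + n_rejected)
  attr(pool, "spec") <- spec
  pool
}

#' Define a ground-truth kinetic model
#'
#' A rate model maps each (substrate class, NNCGNN context) to a first-order
#' methylation rate constant per unit dose, where dose is the product of
#' relative enzyme concentration and incubation time (pseudo-first-order;
#' absolute units are arbitrary).
#'
#' @param rates Tibble with columns `substrate_class`, `context`, `k`
#'   (all `k >= 0`).
#' @param plateau Maximal attainable methylated fraction, in (0, 1].
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(rates, plateau = 1) {
  rates <- as_tibble(rates)
  stopifnot(all(c("substrate_class", "context", "k") %in% names(rates)))
  if (any(rates$k < 0)) abort("all rate constants must be >= 0")
  if (plateau <= 0 || plateau > 1) abort("`plateau` must be in (0, 1]")
  structure(list(rates = rates, plateau = plateau), class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf(
    "<rate_model> %d (class, context) rates, plateau %.3g\n",
    nrow(x$rates), x$plateau
  ))
  invisible(x)
}

# multiplicative per-position base effects encoding the qualitative
# favored/disfavored pattern observed for DNMT1 at the -2..+2 positions
.PROFILE_EFFECTS <- list(
  HM = list(
    `-2` = c(T = 1.50, C = 0.65),
    `-1` = c(C = 1.50, G = 0.65),
    `+1` = c(T = 1.35),
    `+2` = c(A = 1.30, T = 1.30)
  ),
  OH = list(
    `-2` = c(T = 1.55, C = 0.55),
    `-1` = c(C = 1.55, G = 0.55),
    `+1` = c(T = 1.40, A = 0.55),
    `+2` = c(A = 1.30, T = 1.30)
  ),
  UM = list(
    `-2` = c(T = 1.45, G = 0.63, C = 0.63),
    `-1` = c(C = 1.45, G = 0.63),
    `+1` = c(G = 1.45, C = 0.63),
    `+2` = c(A = 1.40, C = 0.68, G = 0.68)
  )
)

context_effect_product <- function(contexts, effects) {
  pos_chars <- list(
    `-2` = substr(contexts, 1L, 1L),
    `-1` = substr(contexts, 2L, 2L),
    `+1` = substr(contexts, 5L, 5L),
    `+2` = substr(contexts, 6L, 6L)
  )
  out <- rep(1, length(contexts))
  for (p in names(effects)) {
    eff <- effects[[p]]
    mult <- eff[pos_chars[[p]]]
    mult[is.na(mult)] <- 1
    out <- out * mult
  }
  unname(out)
}

#' Built-in example rate model
#'
#' Deterministic ground-truth model used as the default study condition for
#' simulations. Per-context rates are products of per-position base effects
#' that encode the qualitative DNMT1 preference pattern (T favored / C
#' disfavored at -2, C favored / G disfavored at -1, class-specific +1/+2
#' effects), giving a roughly 10-fold rate span within the HM class and a
#' roughly 25-fold span within OH and UM. Class geometric means are set to
#' 1 (HM), 1/`hm_oh` (OH) and 1/`hm_um` (UM) per unit dose.
#'
#' @param hm_um Fold preference of HM over UM class geometric means
#'   (default 87).
#' @param hm_oh Fold preference of HM over OH (default 14).
#' @param plateau Maximal methylated fraction (default 1).
#' @return A [rate_model()].
#' @export
#' @examples
#' m <- example_rate_model()
#' dplyr::count(m$rates, substrate_class)
example_rate_model <- function(hm_um = 87, hm_oh = 14, plateau = 1) {
  ctx <- nncgnn_contexts()
  scales <- c(HM = 1, OH = 1 / hm_oh, UM = 1 / hm_um)
  rates <- purrr::map_dfr(c("HM", "OH", "UM"), function(cl) {
    raw <- context_effect_product(ctx, .PROFILE_EFFECTS[[cl]])
    k <- raw / exp(mean(log(raw))) * scales[cl]
    tibble(substrate_class = cl, context = ctx, k = k)
  })
  rate_model(rates, plateau = plateau)
}

lookup_rates <- function(model, substrate_class, context) {
  key <- paste(substrate_class, context, sep = "|")
  tab <- setNames(
    model$rates$k,
    paste(model$rates$substrate_class, model$rates$context, sep = "|")
  )
  k <- unname(tab[key])
  if (anyNA(k)) {
    bad <- unique(key[is.na(k)])
    abort(sprintf(
      "rate model has no entry for context(s): %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  k
}

#' Simulate first-order methylation kinetics on a molecule pool
#'
#' Each unmethylated CpG cytosine is methylated independently with probability
#' `plateau * (1 - exp(-k * dose))`, where `k` is the model's rate constant
#' for the molecule's substrate class and NNCGNN context and dose is the
#' enzyme-concentration multiplier times incubation time. For UM molecules
#' both strands are unmethylated substrates: the upper-strand CpG reacts with
#' the rate of its context and the lower-strand CpG independently with the
#' rate of the reverse-complement context. For HM and OH molecules the lower
#' strand is pre-modified and only the upper strand can react.
#'
#' @param pool Molecule tibble from [generate_pool()].
#' @param model A [rate_model()].
#' @param dose Non-negative dose (relative enzyme concentration x time).
#' @param seed Optional integer seed.
#' @return The pool with `upper_state`/`lower_state` updated and `dose` set.
#' @export
simulate_kinetics <- function(pool, model, dose, seed = NULL) {
  stopifnot(inherits(model, "rate_model"))
  if (dose < 0) abort("`dose` must be non-negative.")
  if (!is.null(seed)) withr::local_seed(seed)

  n <- nrow(pool)
  k_up <- lookup_rates(model, pool$substrate_class, pool$context)
  p_up <- model$plateau * (1 - exp(-k_up * dose))
  can_up <- pool$upper_state == "C"
  hit_up <- can_up & (runif(n) < p_up)

  out <- pool
  out$upper_state <- ifelse(hit_up, "5mC", pool$upper_state)

  is_um <- pool$substrate_class == "UM" & pool$lower_state == "C"
  if (any(is_um)) {
    rc <- revcomp(pool$context[is_um])
    k_lo <- lookup_rates(model, pool$substrate_class[is_um], rc)
    p_lo <- model$plateau * (1 - exp(-k_lo * dose))
    hit_lo <- runif(sum(is_um)) < p_lo
    lower <- out$lower_state
    lower[which(is_um)[hit_lo]] <- "5mC"
    out$lower_state <- lower
  }
  out$dose <- dose
  out
}

apply_sequencing_errors <- function(m, error_rate) {
  if (error_rate <= 0) {
    return(m)
  }
  hit <- which(runif(length(m)) < error_rate)
  if (length(hit) == 0L) {
    return(m)
  }
  cur <- m[hit]
  repl <- random_base_bytes(length(hit))
  same <- repl == cur
  while (any(same)) {
    repl[same] <- random_base_bytes(sum(same))
    same <- repl == cur
  }
  m[hit] <- repl
  m
}

#' Emit hairpin bisulfite read pairs
#'
#' Simulates hairpin ligation followed by bisulfite conversion and paired-end
#' sequencing. Read 1 is the converted upper strand (5'->3'); read 2 is the
#' converted lower strand (5'->3', i.e. reverse-complement orientation),
#' joined to read 1 through the hairpin so both strands of one molecule are
#' read together. Unmethylated cytosines convert to T with probability
#' `conversion`; 5mC and 5hmC are fully protected and read as C. Substitution
#' errors are applied uniformly at `error_rate` per base.
#'
#' @param pool Molecule tibble (after [simulate_kinetics()], or untreated).
#' @param conversion Bisulfite conversion probability in \[0, 1\] (default 1).
#' @param error_rate Per-base substitution error probability (default 0).
#' @param seed Optional integer seed; identical seeds give identical reads.
#' @return Tibble with `molecule_id`, `substrate_class`, `dose`, `read1`,
#'   `read2`.
#' @export
emit_reads <- function(pool, conversion = 1, error_rate = 0, seed = NULL) {
  if (conversion < 0 || conversion > 1) abort("`conversion` must be in [0, 1].")
  if (error_rate < 0 || error_rate > 1) abort("`error_rate` must be in [0, 1].")
  if (!is.null(seed)) withr::local_seed(seed)

  widths <- nchar(pool$sequence)
  out <- vector("list", length(unique(widths)))
  idx_order <- integer(0)
  for (i in seq_along(sort(unique(widths)))) {
    w <- sort(unique(widths))[i]
    rows <- which(widths == w)
    idx_order <- c(idx_order, rows)
    sub <- pool[rows, ]
    m <- seq_to_bytes(sub$sequence)
    nr <- nrow(m)
    ncol_m <- ncol(m)

    # upper strand: all Cs are conversion substrates except a methylated CpG C
    upper <- m
    conv_cand <- upper == .BYTE_C
    prot_idx <- (which(sub$upper_state == "5mC") - 1L) * nr + sub$cpg_pos[sub$upper_state == "5mC"]
    if (length(prot_idx)) conv_cand[prot_idx] <- FALSE
    cand <- which(conv_cand)
    if (length(cand)) {
      converted <- cand[runif(length(cand)) < conversion]
      upper[converted] <- .BYTE_T
    }

    # lower strand aligned to upper coordinates
    lower <- complement_bytes(m)
    conv_cand <- lower == .BYTE_C
    prot <- sub$lower_state %in% c("5mC", "5hmC")
    prot_idx <- (which(prot) - 1L) * nr + (sub$cpg_pos[prot] + 1L)
    if (length(prot_idx)) conv_cand[prot_idx] <- FALSE
    cand <- which(conv_cand)
    if (length(cand)) {
      converted <- cand[runif(length(cand)) < conversion]
      lower[converted] <- .BYTE_T
    }

    upper <- apply_sequencing_errors(upper, error_rate)
    lower <- apply_sequencing_errors(lower, error_rate)

    out[[i]] <- tibble(
      molecule_id = sub$molecule_id,
      substrate_class = sub$substrate_class,
      dose = sub$dose,
      read1 = bytes_to_seq(upper),
      read2 = bytes_to_seq(lower[nr:1L, , drop = FALSE])
    )
  }
  res <- bind_rows(out)
  res[order(idx_order), ]
}

#' Assemble single-amplicon hairpin layout
#'
#' Joins each read pair into one long amplicon `read1 + linker + read2`, the
#' physical layout of a hairpin-ligated, bisulfite-converted molecule. The
#' default linker is a fixed C-free 8-mer so conversion cannot corrupt it.
#'
#' @param reads Tibble from [emit_reads()].
#' @param linker Hairpin linker sequence (C-free by default).
#' @return `reads` with an `amplicon` column added.
#' @export
hairpin_amplicon <- function(reads, linker = "TTGAGGTA") {
  if (grepl("C", linker)) {
    inform("linker contains C; bisulfite conversion would corrupt it on real molecules")
  }
  dplyr::mutate(reads, amplicon = paste0(read1, linker, read2))
}
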