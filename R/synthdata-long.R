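# Long multi-CpG substrates and synthetic genome-scale methylation tables.

#' Generate a long multi-CpG substrate
#'
#' Builds a double-stranded substrate of `length` bp carrying exactly `n_cpg`
#' CpG sites (default 44 sites in 349 bp), with a lower-strand methylation
#' pattern assigned by `pattern_rule` on each site's 4-mer (the CpG plus one
#' base on each side). The default rule marks CCGG and GCGC sites as
#' hemimethylated, emulating a patterned substrate produced by CpG-subset
#' methyltransferases; `n_pattern` sites (default 18) are constructed to
#' match the rule and all others to avoid it.
#'
#' @param seed Optional integer seed.
#' @param n_cpg Number of CpG sites (default 44).
#' @param length Substrate length in bp (default 349).
#' @param pattern_rule Either a character vector of 4-mers (default
#'   `c("CCGG", "GCGC")`) or a predicate function on 4-mer strings deciding
#'   which sites carry lower-strand 5mC.
#' @param n_pattern Number of sites constructed to match the rule when the
#'   rule is a 4-mer set (default 18). Use 0 for a fully unmethylated and
#'   `n_cpg` for a fully hemimethylated substrate. Ignored when
#'   `pattern_rule` is a function.
#' @return An object of class `long_substrate`: list with `sequence` (upper
#'   strand) and `sites`, a tibble with `position` (CpG C, 1-based),
#'   `four_mer`, `context` (NNCGNN), `lower_state` (`"5mC"`/`"C"`) and
#'   `include` flag (all `TRUE`; set to `FALSE` to drop tag-created sites
#'   from analyses).
#' @export
#' @examples
#' sub <- generate_long_substrate(seed = 1)
#' table(sub$sites$lower_state)
generate_long_substrate <- function(seed = NULL, n_cpg = 44L, length = 349L,
                                    pattern_rule = c("CCGG", "GCGC"),
                                    n_pattern = 18L) {
  if (!is.null(seed)) withr::local_seed(seed)
  n_cpg <- as.integer(n_cpg)
  length <- as.integer(length)
  if (n_cpg < 1L) abort("`n_cpg` must be >= 1")

  rule_is_fun <- is.function(pattern_rule)
  matches_rule <- if (rule_is_fun) {
    function(x) vapply(x, pattern_rule, logical(1))
  } else {
    function(x) x %in% pattern_rule
  }
  if (!rule_is_fun) {
    n_pattern <- as.integer(n_pattern)
    if (n_pattern < 0L || n_pattern > n_cpg) {
      abort("`n_pattern` must be between 0 and `n_cpg`")
    }
  }

  # evenly spaced site positions (C of each CpG), jittered, spacing >= 5
  if (n_cpg == 1L) {
    positions <- as.integer(round(length / 2))
  } else {
    span <- length - 8L
    if (span < 5L * (n_cpg - 1L)) abort("substrate too short for `n_cpg` sites")
    base_pos <- round(4L + (seq_len(n_cpg) - 1L) * span / (n_cpg - 1L))
    jitter <- sample(c(-1L, 0L, 1L), n_cpg, replace = TRUE)
    positions <- as.integer(base_pos + jitter)
    positions <- pmax(4L, pmin(length - 4L, positions))
  }

  for (attempt in seq_len(50L)) {
    seq_bytes <- random_base_bytes(length)

    # choose which sites follow the pattern
    if (rule_is_fun) {
      four <- character(n_cpg)
      flank_pairs <- expand.grid(a = .BASES, b = .BASES, stringsAsFactors = FALSE)
      all4 <- paste0(flank_pairs$a, "CG", flank_pairs$b)
      is_match <- matches_rule(all4)
      for (i in seq_len(n_cpg)) four[i] <- sample(all4, 1L)
    } else {
      pat_sites <- sort(sample.int(n_cpg, n_pattern))
      flank_pairs <- expand.grid(a = .BASES, b = .BASES, stringsAsFactors = FALSE)
      all4 <- paste0(flank_pairs$a, "CG", flank_pairs$b)
      match4 <- all4[matches_rule(all4)]
      nomatch4 <- all4[!matches_rule(all4)]
      if (n_pattern > 0L && length(match4) == 0L) {
        abort("pattern rule matches no 4-mer; cannot place pattern sites")
      }
      four <- character(n_cpg)
      four[pat_sites] <- sample(match4, n_pattern, replace = TRUE)
      four[-pat_sites] <- sample(nomatch4, n_cpg - n_pattern, replace = TRUE)
    }

    # write site 4-mers into the sequence
    for (i in seq_len(n_cpg)) {
      idx <- positions[i] + (-1L:2L)
      seq_bytes[idx] <- charToRaw(four[i])
    }

    # break every CG whose C is not a designed site, mutating only
    # non-site positions
    site_span <- unique(as.vector(outer(positions, -1L:2L, `+`)))
    for (pass in seq_len(10L)) {
      cg_c <- which(seq_bytes[-length] == .BYTE_C & seq_bytes[-1L] == .BYTE_G)
      extra <- setdiff(cg_c, positions)
      if (length(extra) == 0L) break
      for (i in extra) {
        if (!(i %in% site_span)) {
          seq_bytes[i] <- .BYTE_T
        } else if (!((i + 1L) %in% site_span)) {
          seq_bytes[i + 1L] <- .BYTE_A
        }
      }
    }
    cg_c <- which(seq_bytes[-length] == .BYTE_C & seq_bytes[-1L] == .BYTE_G)
    if (identical(sort(cg_c), sort(positions))) {
      sequence <- rawToChar(seq_bytes)
      sites <- tibble(position = sort(positions))
      sites$four_mer <- substring(sequence, sites$position - 1L, sites$position + 2L)
      sites$context <- substring(sequence, sites$position - 2L, sites$position + 3L)
      sites$lower_state <- ifelse(matches_rule(sites$four_mer), "5mC", "C")
      sites$include <- TRUE
      return(structure(
        list(sequence = sequence, sites = sites, pattern_rule = pattern_rule),
        class = "long_substrate"
      ))
    }
  }
  abort("could not construct a long substrate satisfying the constraints")
}

#' @export
print.long_substrate <- function(x, ...) {
  cat(sprintf(
    "<long_substrate> %d bp, %d CpG sites (%d hemimethylated, %d unmethylated)\n",
    nchar(x$sequence), nrow(x$sites),
    sum(x$sites$lower_state == "5mC"), sum(x$sites$lower_state == "C")
  ))
  invisible(x)
}

#' Simulate per-site methylation kinetics on a long substrate
#'
#' Draws binomial methylation read counts for every CpG site of a long
#' substrate across a dose series. Hemimethylated sites (lower-strand 5mC)
#' react with the model's HM rate for their context, unmethylated sites with
#' the UM rate.
#'
#' @param substrate A [generate_long_substrate()] object.
#' @param model A [rate_model()].
#' @param doses Numeric vector of doses.
#' @param n_reads Reads per site per dose (default 1000).
#' @param label Substrate label recorded in the output (default
#'   `"patterned"`).
#' @param seed Optional integer seed.
#' @return Site-series tibble: `substrate`, `position`, `context`,
#'   `lower_state`, `dose`, `n_meth`, `n_total`, `fraction`.
#' @export
simulate_long_kinetics <- function(substrate, model, doses, n_reads = 1000L,
                                   label = "patterned", seed = NULL) {
  stopifnot(inherits(substrate, "long_substrate"), inherits(model, "rate_model"))
  if (!is.null(seed)) withr::local_seed(seed)
  sites <- dplyr::filter(substrate$sites, include)
  cls <- ifelse(sites$lower_state == "5mC", "HM", "UM")
  k <- lookup_rates(model, cls, sites$context)
  grid <- tidyr::expand_grid(site = seq_len(nrow(sites)), dose = doses)
  p <- model$plateau * (1 - exp(-k[grid$site] * grid$dose))
  n_meth <- rbinom(nrow(grid), n_reads, p)
  tibble(
    substrate = label,
    position = sites$position[grid$site],
    context = sites$context[grid$site],
    lower_state = sites$lower_state[grid$site],
    dose = grid$dose,
    n_meth = n_meth,
    n_total = as.integer(n_reads),
    fraction = n_meth / n_reads
  )
}

#' Specify a synthetic genome with context-dependent CpG methylation
#'
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_len Chromosome length in bp (default 20000).
#' @param gc_fraction GC content of the random genome (default 0.42,
#'   mammalian-like).
#' @param context_effect Named numeric vector over the 256 NNCGNN contexts
#'   giving each context's mean methylation level in \[0, 1\]. Defaults to a
#'   constant 0.5.
#' @param coverage_mean Mean per-site read depth (Poisson; default 30).
#' @return An object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_chroms = 2L, chrom_len = 20000L,
                                  gc_fraction = 0.42,
                                  context_effect = NULL,
                                  coverage_mean = 30) {
  if (is.null(context_effect)) {
    context_effect <- setNames(rep(0.5, 256L), nncgnn_contexts())
  }
  assert_contexts_complete(names(context_effect), "context_effect")
  if (any(context_effect < 0 | context_effect > 1)) {
    abort("`context_effect` means must be in [0, 1]")
  }
  if (coverage_mean < 0) abort("`coverage_mean` must be >= 0")
  structure(
    list(
      n_chroms = as.integer(n_chroms), chrom_len = as.integer(chrom_len),
      gc_fraction = gc_fraction, context_effect = context_effect,
      coverage_mean = coverage_mean
    ),
    class = "synthetic_genome_spec"
  )
}

#' Simulate a genome FASTA and WGBS-style coverage table
#'
#' Generates a random genome with the requested GC content, locates every
#' upper-strand CpG, and draws per-site methylated read counts
#' `count_meth ~ Binomial(coverage, context_effect[context])` with
#' `coverage ~ Poisson(coverage_mean)`. The coverage table follows the
#' Bismark coverage dialect (1-based inclusive coordinates).
#'
#' @param spec A [synthetic_genome_spec()].
#' @param seed Optional integer seed.
#' @return List with `genome` (named character vector of chromosome
#'   sequences) and `coverage` (tibble: `chrom`, `start`, `end`, `meth_pct`,
#'   `count_meth`, `count_unmeth`).
#' @export
simulate_genomic_table <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  if (!is.null(seed)) withr::local_seed(seed)
  gc <- spec$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  genome <- character(spec$n_chroms)
  names(genome) <- paste0("chr", seq_len(spec$n_chroms))
  cov_rows <- vector("list", spec$n_chroms)
  for (i in seq_len(spec$n_chroms)) {
    bases <- sample(.BASES, spec$chrom_len, replace = TRUE, prob = probs)
    chrom_seq <- paste(bases, collapse = "")
    genome[i] <- chrom_seq
    b <- charToRaw(chrom_seq)
    pos <- which(b[-length(b)] == .BYTE_C & b[-1L] == .BYTE_G)
    pos <- pos[pos >= 3L & pos <= spec$chrom_len - 3L]
    if (length(pos) == 0L) next
    ctx <- substring(chrom_seq, pos - 2L, pos + 3L)
    coverage <- rpois(length(pos), spec$coverage_mean)
    p <- unname(spec$context_effect[ctx])
    count_meth <- rbinom(length(pos), coverage, p)
    cov_rows[[i]] <- tibble(
      chrom = names(genome)[i],
      start = pos, end = pos,
      meth_pct = ifelse(coverage > 0, 100 * count_meth / coverage, NA_real_),
      count_meth = count_meth,
      count_unmeth = coverage - count_meth
    )
  }
  list(genome = genome, coverage = bind_rows(cov_rows))
}
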