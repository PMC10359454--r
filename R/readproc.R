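# Hairpin bisulfite read processing: reconstruct the original molecule from
# the converted upper- and lower-strand reads, call CpG methylation on both
# strands, demultiplex by substrate barcode, and tabulate per-context counts.

# base code 0..4 for A,C,G,T,other
.CODE_TABLE <- local({
  tab <- rep(4L, 256L)
  tab[66L] <- 0L # A
  tab[68L] <- 1L # C
  tab[72L] <- 2L # G
  tab[85L] <- 3L # T
  tab
})

# original upper-strand base implied by (upper read base, aligned lower read
# base); contradictions yield N
.RECON_TABLE <- local({
  tab <- matrix(.BYTE_N, nrow = 5L, ncol = 5L) # rows upper, cols lower
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  tab[code["A"], code["T"]] <- .BYTE_A # A/T pair
  tab[code["C"], code["G"]] <- .BYTE_C # protected upper C
  tab[code["G"], code["C"]] <- .BYTE_G # lower C protected
  tab[code["G"], code["T"]] <- .BYTE_G # lower C converted
  tab[code["T"], code["G"]] <- .BYTE_C # upper C converted
  tab[code["T"], code["A"]] <- .BYTE_T # genuine T
  tab
})

#' Reconstruct original molecules from hairpin read pairs
#'
#' Applies the strand-reconstruction rule table position by position: an
#' upper-strand C is protected (original C); an upper T over a lower G is a
#' converted C; an upper T over a lower A is a genuine T; an upper G over a
#' lower T means the lower-strand C was converted; A/T pairs are carried
#' through; any other combination is a contradiction and the position is
#' flagged ambiguous (N in the output). Pairs whose reads differ in length
#' are discarded and counted in the `n_discarded` attribute.
#'
#' @param reads Tibble with `read1` (converted upper strand, 5'->3') and
#'   `read2` (converted lower strand, 5'->3'); other columns are carried
#'   through.
#' @return The input rows with equal-length pairs only, plus `original`
#'   (reconstructed upper-strand sequence, N at ambiguous positions) and
#'   `n_ambiguous` (count of ambiguous positions). Attribute `n_discarded`
#'   holds the number of length-mismatched pairs removed.
#' @export
reconstruct_hairpin <- function(reads) {
  stopifnot(all(c("read1", "read2") %in% names(reads)))
  w1 <- nchar(reads$read1)
  keep <- w1 == nchar(reads$read2)
  n_discarded <- sum(!keep)
  reads <- reads[keep, ]
  w1 <- w1[keep]

  out <- vector("list", 0L)
  orig <- character(nrow(reads))
  n_amb <- integer(nrow(reads))
  for (w in unique(w1)) {
    rows <- which(w1 == w)
    u <- seq_to_bytes(reads$read1[rows])
    l <- seq_to_bytes(reads$read2[rows])[w:1L, , drop = FALSE] # align to upper coords
    cu <- .CODE_TABLE[as.integer(u) + 1L]
    cl <- .CODE_TABLE[as.integer(l) + 1L]
    om <- .RECON_TABLE[cbind(cu + 1L, cl + 1L)]
    dim(om) <- dim(u)
    orig[rows] <- bytes_to_seq(om)
    n_amb[rows] <- colSums(om == .BYTE_N)
  }
  res <- reads
  res$original <- orig
  res$n_ambiguous <- n_amb
  attr(res, "n_discarded") <- n_discarded
  res
}

#' Call CpG methylation on reconstructed molecules
#'
#' For each reconstructed molecule, calls the methylation state of the upper
#' and lower strand at the CpG and extracts the flanking context from the
#' reconstructed original sequence. The upper strand is methylated iff the
#' upper read retained C at the CpG C; the lower strand is methylated iff the
#' lower read retained C at the position pairing the CpG G. Records whose
#' NNCGNN window contains an ambiguous base are marked ambiguous and are
#' excluded from downstream counts.
#'
#' @param recon Tibble from [reconstruct_hairpin()].
#' @param cpg_pos Position (1-based) of the CpG C on the upper strand.
#' @param flank_len Flank length used for the extracted window (default 10).
#' @return Call-record tibble: carried-through metadata plus `original`,
#'   `flank_window` (positions -flank_len..-1, CpG, +1..+flank_len),
#'   `nncgnn`, `call_upper`, `call_lower` (each `"methylated"`,
#'   `"unmethylated"` or `"ambiguous"`).
#' @export
call_cpg <- function(recon, cpg_pos, flank_len = 10L) {
  w <- nchar(recon$read1)
  if (any(cpg_pos + 1L > w) || any(cpg_pos < 3L)) {
    abort("`cpg_pos` outside read for some records")
  }
  u_c <- substr(recon$read1, cpg_pos, cpg_pos)
  u_g <- substr(recon$read1, cpg_pos + 1L, cpg_pos + 1L)
  # aligned lower base at upper position i sits at read2 position w - i + 1
  l_c <- substr(recon$read2, w - cpg_pos + 1L, w - cpg_pos + 1L)
  l_g <- substr(recon$read2, w - cpg_pos, w - cpg_pos)

  call_upper <- dplyr::case_when(
    u_c == "C" & l_c == "G" ~ "methylated",
    u_c == "T" & l_c == "G" ~ "unmethylated",
    TRUE ~ "ambiguous"
  )
  call_lower <- dplyr::case_when(
    l_g == "C" & u_g == "G" ~ "methylated",
    l_g == "T" & u_g == "G" ~ "unmethylated",
    TRUE ~ "ambiguous"
  )

  nncgnn <- substr(recon$original, cpg_pos - 2L, cpg_pos + 3L)
  window <- substr(recon$original, cpg_pos - flank_len, cpg_pos + 1L + flank_len)
  bad <- grepl("N", nncgnn) | substr(nncgnn, 3L, 4L) != "CG"
  call_upper[bad] <- "ambiguous"
  call_lower[bad] <- "ambiguous"

  out <- recon
  out$flank_window <- window
  out$nncgnn <- nncgnn
  out$call_upper <- call_upper
  out$call_lower <- call_lower
  out$read1 <- NULL
  out$read2 <- NULL
  out
}

match_barcode <- function(read1, barcode, max_mismatch = 0L) {
  bl <- nchar(barcode)
  prefix <- substr(read1, 1L, bl)
  if (max_mismatch == 0L) {
    return(prefix == barcode)
  }
  pb <- seq_to_bytes(prefix)
  bb <- charToRaw(barcode)
  colSums(pb != bb) <= max_mismatch
}

#' Demultiplex read pairs by substrate barcode
#'
#' Assigns each read pair to a substrate class by exact match of the
#' class-specific barcode at the start of read 1 (1-mismatch tolerance via
#' `max_mismatch = 1`). Barcodes containing C are additionally matched in
#' their bisulfite-converted (C->T) form. Unmatched reads are routed to an
#' `"unassigned"` bucket, never dropped silently.
#'
#' @param reads Tibble with a `read1` column.
#' @param specs List of [substrate_spec()] objects (one per class).
#' @param max_mismatch Allowed barcode mismatches (default 0).
#' @return `reads` with the `substrate_class` column set.
#' @export
demultiplex_reads <- function(reads, specs, max_mismatch = 0L) {
  cls <- rep("unassigned", nrow(reads))
  for (spec in specs) {
    hit <- match_barcode(reads$read1, spec$barcode, max_mismatch)
    if (grepl("C", spec$barcode)) {
      hit <- hit | match_barcode(
        reads$read1, gsub("C", "T", spec$barcode), max_mismatch
      )
    }
    cls[hit & cls == "unassigned"] <- spec$substrate_class
  }
  reads$substrate_class <- cls
  reads
}

#' Process hairpin read pairs into call records
#'
#' Full read-processing pipeline: demultiplex by barcode, filter pairs
#' against the expected substrate size (+/- `length_tol` bp), reconstruct
#' the original molecules, and call CpG methylation. Discarded and ambiguous
#' reads are counted in the attached QC report.
#'
#' @param reads Tibble from [emit_reads()] or [read_fastq_pairs()].
#' @param specs List of [substrate_spec()] objects.
#' @param max_mismatch Barcode mismatches allowed (default 0).
#' @param length_tol Length filter tolerance in bp (default 2).
#' @return Call-record tibble (see [call_cpg()]); attribute `qc` is a list
#'   with counts of reads in, assigned, discarded by length, unassigned and
#'   ambiguous.
#' @export
process_read_pairs <- function(reads, specs, max_mismatch = 0L, length_tol = 2L) {
  n_in <- nrow(reads)
  if (!"substrate_class" %in% names(reads) ||
    any(is.na(reads$substrate_class))) {
    reads <- demultiplex_reads(reads, specs, max_mismatch)
  }
  spec_by_class <- setNames(specs, vapply(specs, `[[`, "", "substrate_class"))

  records <- vector("list", length(spec_by_class))
  n_len_discard <- 0L
  n_pair_discard <- 0L
  for (i in seq_along(spec_by_class)) {
    spec <- spec_by_class[[i]]
    sub <- dplyr::filter(reads, substrate_class == spec$substrate_class)
    if (nrow(sub) == 0L) next
    ok_len <- abs(nchar(sub$read1) - spec$total_len) <= length_tol &
      abs(nchar(sub$read2) - spec$total_len) <= length_tol
    n_len_discard <- n_len_discard + sum(!ok_len)
    sub <- sub[ok_len, ]
    if (nrow(sub) == 0L) next
    recon <- reconstruct_hairpin(sub)
    n_pair_discard <- n_pair_discard + attr(recon, "n_discarded")
    records[[i]] <- call_cpg(recon, spec$cpg_pos, spec$flank_len)
  }
  out <- bind_rows(records)
  n_ambiguous <- if (nrow(out)) {
    sum(out$call_upper == "ambiguous" | out$call_lower == "ambiguous")
  } else {
    0L
  }
  attr(out, "qc") <- list(
    reads_in = n_in,
    assigned = if (nrow(reads)) sum(reads$substrate_class != "unassigned") else 0L,
    unassigned = if (nrow(reads)) sum(reads$substrate_class == "unassigned") else 0L,
    discarded_length = n_len_discard,
    discarded_pairing = n_pair_discard,
    ambiguous = n_ambiguous
  )
  out
}

#' Tabulate methylation calls per NNCGNN context
#'
#' Aggregates call records into per-(class, dose, context) methylated/total
#' counts. For HM and OH substrates only upper-strand calls count (the lower
#' strand is pre-modified). For UM substrates both strands are substrates;
#' under the default `"per_strand"` policy each strand contributes an
#' independent event, with lower-strand events assigned to the
#' reverse-complement context (the lower strand's own orientation). The
#' `"per_molecule"` policy instead counts one event per UM molecule,
#' methylated if either strand is methylated, under the upper-strand
#' context. Ambiguous calls are excluded.
#'
#' @param records Call-record tibble from [call_cpg()] /
#'   [process_read_pairs()].
#' @param um_policy `"per_strand"` (default) or `"per_molecule"`.
#' @return Context count tibble: `substrate_class`, `dose`, `context`,
#'   `n_meth`, `n_total`.
#' @export
tabulate_contexts <- function(records, um_policy = c("per_strand", "per_molecule")) {
  um_policy <- arg_match(um_policy)
  if (!"dose" %in% names(records)) records$dose <- NA_real_

  upper <- records %>%
    filter(call_upper != "ambiguous", substrate_class %in% c("HM", "OH", "UM")) %>%
    mutate(context = nncgnn, meth = call_upper == "methylated") %>%
    select(substrate_class, dose, context, meth)

  events <- upper
  um <- filter(records, substrate_class == "UM")
  if (nrow(um) > 0L) {
    if (um_policy == "per_strand") {
      lower <- um %>%
        filter(call_lower != "ambiguous") %>%
        mutate(context = revcomp(nncgnn), meth = call_lower == "methylated") %>%
        select(substrate_class, dose, context, meth)
      events <- bind_rows(events, lower)
    } else {
      events <- events %>%
        filter(!(substrate_class == "UM"))
      mol <- um %>%
        filter(call_upper != "ambiguous", call_lower != "ambiguous") %>%
        mutate(
          context = nncgnn,
          meth = call_upper == "methylated" | call_lower == "methylated"
        ) %>%
        select(substrate_class, dose, context, meth)
      events <- bind_rows(events, mol)
    }
  }

  events %>%
    group_by(substrate_class, dose, context) %>%
    summarise(n_meth = sum(meth), n_total = dplyr::n(), .groups = "drop") %>%
    arrange(substrate_class, dose, context)
}

#' Estimate false-methylation background from a no-enzyme control
#'
#' Pools methylated over total counts per substrate class from a zero-dose
#' control; the result is exposed for optional background subtraction
#' (disabled by default throughout the package).
#'
#' @param counts Context count tibble from [tabulate_contexts()] for a
#'   control reaction without enzyme.
#' @return Tibble with `substrate_class`, `n_meth`, `n_total`, `background`
#'   (`NA` when the class has no reads).
#' @export
estimate_background <- function(counts) {
  counts %>%
    group_by(substrate_class) %>%
    summarise(
      n_meth = sum(n_meth), n_total = sum(n_total),
      .groups = "drop"
    ) %>%
    mutate(background = ifelse(n_total > 0, n_meth / n_total, NA_real_))
}
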