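# Readers and writers for the standard plain-text interchange formats:
# FASTQ read pairs (via Biostrings), rate-table TSV (the dialect of the
# published per-NNCGNN rate data sets), Bismark-style coverage TSV, and the
# ground-truth sidecar emitted next to simulated reads.

#' Write hairpin read pairs as FASTQ files
#'
#' Writes 4-line FASTQ records with a constant Phred+33 quality. Output is
#' byte-identical for identical input, so simulated runs are reproducible at
#' the file level.
#'
#' @param reads Tibble from [emit_reads()].
#' @param r1_path,r2_path Output paths for read 1 / read 2.
#' @param quality Constant quality character (default `"I"`, Q40).
#' @return Invisibly, the paths.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path, quality = "I") {
  ids <- paste0(
    reads$molecule_id, " class=", reads$substrate_class,
    " dose=", reads$dose
  )
  write_one <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    quals <- Biostrings::BStringSet(strrep(quality, nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  }
  write_one(reads$read1, r1_path)
  write_one(reads$read2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read hairpin read pairs from FASTQ files
#'
#' @param r1_path,r2_path FASTQ paths written by [write_fastq_pairs()] or an
#'   equivalent pipeline. Read headers of the form
#'   `id class=<HM|OH|UM> dose=<x>` are parsed back into columns when
#'   present.
#' @return Tibble with `molecule_id`, `substrate_class`, `dose`, `read1`,
#'   `read2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(r1) != length(r2)) abort("read files differ in record count")
  ids <- names(r1)
  cls <- stringr::str_match(ids, "class=(\\S+)")[, 2]
  dose <- suppressWarnings(as.numeric(stringr::str_match(ids, "dose=(\\S+)")[, 2]))
  tibble(
    molecule_id = stringr::str_extract(ids, "^\\S+"),
    substrate_class = cls,
    dose = dose,
    read1 = as.character(r1),
    read2 = as.character(r2)
  )
}

#' Write the ground-truth sidecar for a simulated pool
#'
#' @param pool Molecule tibble (after [simulate_kinetics()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(pool, path) {
  sidecar <- dplyr::transmute(
    pool,
    molecule_id, context,
    substrate_class, dose,
    methylated = as.integer(upper_state == "5mC")
  )
  readr::write_tsv(sidecar, path)
  invisible(path)
}

#' Write and read per-context rate tables
#'
#' The TSV dialect has columns `context`, `substrate_class`, `k`, `sem`, `n`
#' and round-trips losslessly. `read_rate_table()` also reads externally
#' produced per-NNCGNN rate tables (such as published supplementary data
#' sets) through the `col_map` argument, which renames the file's columns to
#' the package's names.
#'
#' @param rates Rate table tibble (`substrate_class`, `context`, `k`,
#'   optionally `sem`, `n`).
#' @param path TSV path.
#' @param col_map Named character vector mapping package column names to the
#'   file's column names, e.g.
#'   `c(context = "NNCGNN", k = "rate_HM", sem = "SEM_HM")`.
#' @param substrate_class Class label to assign when the file holds one
#'   class per column set rather than a class column.
#' @return `write_rate_table()` returns `path` invisibly;
#'   `read_rate_table()` returns the rate table tibble.
#' @export
write_rate_table <- function(rates, path) {
  cols <- intersect(c("context", "substrate_class", "k", "sem", "n"), names(rates))
  readr::write_tsv(rates[, cols], path)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path, col_map = NULL, substrate_class = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(raw)) {
        abort(sprintf("column `%s` not found in %s", col_map[[nm]], path))
      }
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  if (!is.null(substrate_class)) raw$substrate_class <- substrate_class
  need <- c("context", "substrate_class", "k")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(sprintf("rate table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(raw[, intersect(c(need, "sem", "n"), names(raw))])
  bad <- !is_nncgnn(out$context)
  if (any(bad)) {
    abort(sprintf(
      "%d rows have malformed NNCGNN contexts (first: %s)",
      sum(bad), out$context[which(bad)[1]]
    ))
  }
  out
}

#' Write and read genome FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path FASTA path.
#' @return `write_genome_fasta()` returns `path` invisibly;
#'   `read_genome_fasta()` returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write and read Bismark-style coverage tables
#'
#' Columns: chrom, start, end (1-based inclusive), methylation percentage,
#' methylated count, unmethylated count; tab-separated, no header.
#'
#' @param coverage Coverage tibble (`chrom`, `start`, `end`, `meth_pct`,
#'   `count_meth`, `count_unmeth`).
#' @param path TSV path.
#' @return `write_coverage_tsv()` returns `path` invisibly;
#'   `read_coverage_tsv()` returns the coverage tibble.
#' @export
write_coverage_tsv <- function(coverage, path) {
  readr::write_tsv(
    coverage[, c("chrom", "start", "end", "meth_pct", "count_meth", "count_unmeth")],
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @export
read_coverage_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "meth_pct", "count_meth", "count_unmeth"),
    col_types = "ciidii",
    progress = FALSE
  )
}
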