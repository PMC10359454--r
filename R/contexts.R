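#' All 256 NNCGNN flanking contexts
#'
#' Enumerates the 4^4 = 256 six-base contexts consisting of a central CpG
#' dinucleotide and two flanking bases on each side, in lexicographic order.
#' This ordering is the canonical context axis used by rate tables, preference
#' profiles and genomic methylation profiles throughout the package.
#'
#' @return Character vector of length 256, each element a 6-mer with "CG" at
#'   positions 3--4 (e.g. `"AACGAA"`, ..., `"TTCGTT"`).
#' @export
#' @examples
#' head(nncgnn_contexts())
nncgnn_contexts <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(n4 = b, n3 = b, n2 = b, n1 = b, stringsAsFactors = FALSE)
  ctx <- paste0(g$n1, g$n2, "CG", g$n3, g$n4)
  sort(ctx)
}

#' Reverse complement of DNA sequences
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] for plain
#' character vectors.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GACGTA")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_nncgnn <- function(x) {
  nchar(x) == 6L & substr(x, 3L, 4L) == "CG" &
    !grepl("[^ACGT]", x)
}

assert_contexts_complete <- function(contexts, where = "rate table") {
  missing <- setdiff(nncgnn_contexts(), contexts)
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing %d NNCGNN contexts (first few: %s)",
      where, length(missing), paste(head(missing, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

# ---- internal byte-level sequence helpers -----------------------------------
# Fixed-width sequence sets are manipulated as raw byte matrices (one column
# per molecule) which keeps per-base operations vectorized over millions of
# bases without materializing per-character R vectors.

.BYTE_A <- as.raw(65L)
.BYTE_C <- as.raw(67L)
.BYTE_G <- as.raw(71L)
.BYTE_N <- as.raw(78L)
.BYTE_T <- as.raw(84L)

# nrow = sequence width, ncol = number of sequences
seq_to_bytes <- function(x) {
  w <- nchar(x[1])
  stopifnot(all(nchar(x) == w))
  matrix(charToRaw(paste(x, collapse = "")), nrow = w)
}

bytes_to_seq <- function(m) {
  s <- rawToChar(as.raw(m))
  w <- nrow(m)
  if (is.null(w)) w <- length(m)
  starts <- seq.int(1L, by = w, length.out = length(m) / w)
  substring(s, starts, starts + w - 1L)
}

.COMP_TABLE <- local({
  tab <- rep(as.raw(78L), 256L) # everything else -> N
  tab[66L] <- as.raw(84L) # A -> T
  tab[68L] <- as.raw(71L) # C -> G
  tab[72L] <- as.raw(67L) # G -> C
  tab[85L] <- as.raw(65L) # T -> A
  tab[79L] <- as.raw(78L) # N -> N
  tab
})

complement_bytes <- function(m) {
  out <- .COMP_TABLE[as.integer(m) + 1L]
  dim(out) <- dim(m)
  out
}

# count CG dinucleotides per column
count_cg <- function(m) {
  nr <- nrow(m)
  if (nr < 2L) {
    return(rep(0L, ncol(m)))
  }
  hits <- (m[-nr, , drop = FALSE] == .BYTE_C) &
    (m[-1L, , drop = FALSE] == .BYTE_G)
  colSums(hits)
}

.BASES <- c("A", "C", "G", "T")
.BASE_BYTES <- c(.BYTE_A, .BYTE_C, .BYTE_G, .BYTE_T)

random_base_bytes <- function(n) {
  .BASE_BYTES[sample.int(4L, n, replace = TRUE)]
}
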