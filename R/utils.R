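# Internal coordinate and sequence helpers.
#
# Convention used throughout the package: genomic coordinates are 1-based
# inclusive; positions relative to a TSS (or to the first base of a start
# codon) skip 0, so -1 is the base immediately 5' of +1 and +1 is the
# reference base itself.

#' Reverse complement of character DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
#' @noRd
.revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1L]]
    paste0(rev(ch), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Map a TSS-relative position (no 0) to a genomic coordinate
#'
#' @param pos 1-based genomic position of the +1 base.
#' @param strand "+" or "-".
#' @param rel signed relative position; must not be 0.
#' @keywords internal
#' @noRd
.relToGenomic <- function(pos, strand, rel) {
  stopifnot(all(rel != 0L))
  n <- max(length(pos), length(rel))
  pos <- rep_len(pos, n)
  rel <- rep_len(rel, n)
  if (strand == "+") {
    ifelse(rel < 0L, pos + rel, pos + rel - 1L)
  } else {
    ifelse(rel < 0L, pos - rel, pos - rel + 1L)
  }
}

#' Sequence of relative-position labels starting at `from`, skipping 0
#' @keywords internal
#' @noRd
.relLabels <- function(from, n) {
  labs <- seq(from, length.out = n + 1L)
  labs <- labs[labs != 0L]
  labs[seq_len(n)]
}

#' Position labels of a window covering -up..-1, +1..+down
#' @keywords internal
#' @noRd
windowPositions <- function(upstream, downstream) {
  c(seq.int(-upstream, -1L), seq_len(downstream))
}

#' Count-weighted population standard deviation of positions
#'
#' The clustering and merge rules are expressed in terms of the standard
#' deviation of read 5'-end positions; reads are summarized per position,
#' so the SD is the population SD of positions weighted by read counts
#' (denominator = total reads).
#'
#' @param positions numeric vector of genomic positions.
#' @param counts non-negative weights (read counts), same length.
#' @return weighted population SD in nt.
#' @export
#' @examples
#' weightedSd(c(1000, 1003), c(20, 5))
weightedSd <- function(positions, counts) {
  stopifnot(length(positions) == length(counts), all(counts >= 0))
  tot <- sum(counts)
  if (tot == 0) return(0)
  mu <- sum(counts * positions) / tot
  sqrt(sum(counts * (positions - mu)^2) / tot)
}

#' Extract a strand-oriented subsequence from a genome
#'
#' @param genome character scalar (whole genome) or DNAStringSet of length 1.
#' @param start,end 1-based inclusive genomic coordinates.
#' @param strand "+" or "-"; on "-" the reverse complement is returned.
#' @keywords internal
#' @noRd
.extractRegion <- function(genome, start, end, strand) {
  g <- .genomeChar(genome)
  s <- substr(g, start, end)
  if (strand == "-") s <- .revcomp(s)
  s
}

#' Coerce genome representations to a single uppercase character string
#' @keywords internal
#' @noRd
.genomeChar <- function(genome) {
  if (is.character(genome)) {
    if (length(genome) != 1L) stop("genome must be a single sequence")
    return(toupper(genome))
  }
  if (methods::is(genome, "DNAStringSet")) {
    if (length(genome) != 1L) stop("genome must contain a single record")
    return(as.character(genome[[1L]]))
  }
  if (methods::is(genome, "DNAString")) return(as.character(genome))
  stop("unsupported genome representation: ", class(genome)[1L])
}

#' Genome length helper
#' @keywords internal
#' @noRd
.genomeLen <- function(genome) nchar(.genomeChar(genome))

# IUPAC degenerate nucleotide codes as base sets
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Sample a concrete sequence from an IUPAC pattern
#' @keywords internal
#' @noRd
.sampleIupac <- function(pattern) {
  letters <- strsplit(pattern, "")[[1L]]
  bad <- setdiff(letters, names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  paste0(vapply(letters, function(l) {
    opts <- .IUPAC[[l]]
    opts[sample.int(length(opts), 1L)]
  }, character(1L)), collapse = "")
}
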