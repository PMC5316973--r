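# S4 containers for per-base 5'-end / coverage signal and motif models.

#' Per-base 5'-end read-count profile for one sequencing library
#'
#' Dense per-strand integer vectors holding, at every genomic position, the
#' number of read 5' ends mapping there. One object corresponds to one
#' library (TEX-treated, TEX-untreated, or strand-specific RNA-seq).
#'
#' @slot libraryKind one of \code{"TEX_PLUS"}, \code{"TEX_MINUS"},
#'   \code{"SSRNA"}.
#' @slot fwd integer vector, counts on the forward strand; its length is the
#'   genome length.
#' @slot rev integer vector, counts on the reverse strand, same length.
#' @export
setClass("FivePrimeProfile",
  representation(libraryKind = "character", fwd = "integer", rev = "integer"))

setValidity("FivePrimeProfile", function(object) {
  msgs <- character()
  if (!object@libraryKind %in% c("TEX_PLUS", "TEX_MINUS", "SSRNA"))
    msgs <- c(msgs, "libraryKind must be TEX_PLUS, TEX_MINUS or SSRNA")
  if (length(object@fwd) != length(object@rev))
    msgs <- c(msgs, "fwd and rev must have equal length")
  if (anyNA(object@fwd) || anyNA(object@rev))
    msgs <- c(msgs, "counts must not be NA")
  else if (any(object@fwd < 0L) || any(object@rev < 0L))
    msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FivePrimeProfile
#'
#' @param libraryKind \code{"TEX_PLUS"}, \code{"TEX_MINUS"} or \code{"SSRNA"}.
#' @param fwd,rev integer vectors of per-position 5'-end counts (forward /
#'   reverse strand), each of length equal to the genome length.
#' @return a \linkS4class{FivePrimeProfile}.
#' @export
FivePrimeProfile <- function(libraryKind, fwd, rev) {
  methods::new("FivePrimeProfile", libraryKind = libraryKind,
               fwd = as.integer(fwd), rev = as.integer(rev))
}

#' Per-base coverage profile (possibly normalized, hence real-valued)
#'
#' @slot fwd,rev numeric vectors of per-position depth on the two strands.
#' @export
setClass("CoverageProfile", representation(fwd = "numeric", rev = "numeric"))

setValidity("CoverageProfile", function(object) {
  if (length(object@fwd) != length(object@rev))
    return("fwd and rev must have equal length")
  if (any(object@fwd < 0, na.rm = TRUE) || any(object@rev < 0, na.rm = TRUE))
    return("depths must be non-negative")
  TRUE
})

#' Construct a CoverageProfile
#'
#' @param fwd,rev numeric per-position depth vectors (forward / reverse).
#' @return a \linkS4class{CoverageProfile}.
#' @export
CoverageProfile <- function(fwd, rev) {
  methods::new("CoverageProfile", fwd = as.numeric(fwd), rev = as.numeric(rev))
}

#' Library kind of a profile
#' @param x a \linkS4class{FivePrimeProfile}.
#' @return character scalar.
#' @export
libraryKind <- function(x) x@libraryKind

#' Per-strand signal vector of a profile
#' @param x a \linkS4class{FivePrimeProfile} or \linkS4class{CoverageProfile}.
#' @param strand \code{"+"} or \code{"-"}.
#' @return numeric/integer vector of per-position signal.
#' @export
strandSignal <- function(x, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (strand == "+") x@fwd else x@rev
}

#' Genome length covered by a profile
#' @param x a profile object.
#' @return integer scalar.
#' @export
profileLength <- function(x) length(x@fwd)

setMethod("show", "FivePrimeProfile", function(object) {
  cat(sprintf("FivePrimeProfile [%s], genome length %d\n",
              object@libraryKind, length(object@fwd)))
  cat(sprintf("  total 5' ends: fwd %d, rev %d; nonzero positions: %d\n",
              sum(object@fwd), sum(object@rev),
              sum(object@fwd > 0L) + sum(object@rev > 0L)))
})

setMethod("show", "CoverageProfile", function(object) {
  cat(sprintf("CoverageProfile, genome length %d\n", length(object@fwd)))
  cat(sprintf("  total depth: fwd %.1f, rev %.1f\n",
              sum(object@fwd), sum(object@rev)))
})

#' Fixed-width nucleotide motif model (position frequency matrix)
#'
#' @slot width motif width in nt.
#' @slot counts 4 x width matrix of (expected) base counts, rows A,C,G,T.
#' @slot freq 4 x width column-stochastic frequency matrix.
#' @slot pseudocount pseudocount added per cell during estimation.
#' @slot background length-4 0-order background frequencies.
#' @slot consensus IUPAC consensus string.
#' @slot information per-position information content in bits (uniform
#'   background), in [0, 2].
#' @slot logLik final model log-likelihood.
#' @slot gamma estimated fraction of sequences carrying an occurrence.
#' @export
setClass("MotifModel",
  representation(width = "integer", counts = "matrix", freq = "matrix",
                 pseudocount = "numeric", background = "numeric",
                 consensus = "character", information = "numeric",
                 logLik = "numeric", gamma = "numeric"))

setValidity("MotifModel", function(object) {
  msgs <- character()
  if (ncol(object@freq) != object@width || nrow(object@freq) != 4L)
    msgs <- c(msgs, "freq must be a 4 x width matrix")
  if (any(abs(colSums(object@freq) - 1) > 1e-9))
    msgs <- c(msgs, "freq columns must sum to 1")
  if (any(object@information < -1e-9 | object@information > 2 + 1e-9))
    msgs <- c(msgs, "information content must lie in [0, 2] bits")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel: width %d, consensus %s\n",
              object@width, object@consensus))
  cat(sprintf("  total information %.2f bits, occurrence rate %.2f, logLik %.2f\n",
              sum(object@information), object@gamma, object@logLik))
})

#' Frequency matrix of a motif model
#' @param x a \linkS4class{MotifModel}.
#' @return 4 x width matrix with rows A,C,G,T.
#' @export
frequencyMatrix <- function(x) x@freq

#' IUPAC consensus of a motif model
#' @param x a \linkS4class{MotifModel}.
#' @return character scalar.
#' @export
motifConsensus <- function(x) x@consensus

#' Per-position information content of a motif model
#' @param x a \linkS4class{MotifModel}.
#' @return numeric vector of bits per position.
#' @export
informationContent <- function(x) x@information
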