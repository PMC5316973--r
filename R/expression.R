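# Per-gene quantification, per-million normalization, fold-change screen.

#' Sum strand-matched signal over gene bodies
#'
#' rRNA/tRNA genes are excluded from counting and from the normalization
#' denominator. Overlapping same-strand genes both receive the shared
#' signal (interval-sum semantics; a warning notes the double-counting).
#'
#' @param profile a \linkS4class{CoverageProfile} or
#'   \linkS4class{FivePrimeProfile}.
#' @param annotation GRanges with gene_id and feature_kind mcols.
#' @return list with \code{counts} (named numeric, CDS genes only),
#'   \code{library_total} (total profile signal minus rRNA/tRNA signal),
#'   \code{excluded} (gene_ids of structural RNAs).
#' @export
countPerGene <- function(profile, annotation) {
  fwd <- strandSignal(profile, "+")
  rev <- strandSignal(profile, "-")
  st <- as.character(GenomicRanges::strand(annotation))
  s <- GenomicRanges::start(annotation)
  e <- GenomicRanges::end(annotation)
  kind <- annotation$feature_kind
  sums <- vapply(seq_along(annotation), function(i) {
    v <- if (st[i] == "+") fwd else rev
    sum(v[s[i]:e[i]])
  }, numeric(1L))
  cds <- kind == "CDS"
  # overlap warning: same-strand CDS genes sharing bases
  gr_cds <- annotation[cds]
  ov <- GenomicRanges::findOverlaps(gr_cds, gr_cds, ignore.strand = FALSE)
  ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
  if (length(ov))
    warning(length(ov), " overlapping same-strand gene pair(s): ",
            "shared signal counted for both")
  structural_total <- sum(sums[!cds])
  list(counts = stats::setNames(sums[cds], annotation$gene_id[cds]),
       library_total = sum(fwd) + sum(rev) - structural_total,
       excluded = annotation$gene_id[!cds])
}

#' Scale counts to reads per million
#'
#' @param counts numeric vector of raw per-gene counts.
#' @param library_total the library's total mapped signal after rRNA/tRNA
#'   exclusion; defaults to \code{sum(counts)}.
#' @return counts x 1e6 / library_total.
#' @export
normalizePerMillion <- function(counts, library_total = sum(counts)) {
  if (library_total <= 0) stop("library total must be positive")
  counts * 1e6 / library_total
}

#' Build a per-gene, per-condition expression table
#'
#' @param profiles named list of \linkS4class{CoverageProfile}s, one per
#'   condition.
#' @param annotation GRanges annotation.
#' @return data.frame gene_id, condition, raw, normalized.
#' @export
expressionTable <- function(profiles, annotation) {
  out <- lapply(names(profiles), function(cond) {
    cp <- countPerGene(profiles[[cond]], annotation)
    data.frame(gene_id = names(cp$counts), condition = cond,
               raw = unname(cp$counts),
               normalized = unname(normalizePerMillion(cp$counts,
                                                       cp$library_total)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fold-change screen between two conditions
#'
#' ratio = (normalized_a + pseudocount) / (normalized_b + pseudocount); a
#' gene passes iff ratio >= min_fold or <= 1/min_fold.
#'
#' @param expr expression table from \code{\link{expressionTable}} (ratios
#'   are computed on the normalized scale).
#' @param cond_a,cond_b condition labels (a is the numerator).
#' @param min_fold fold-change threshold (>= 1).
#' @param pseudocount pseudocount on the normalized scale.
#' @return data.frame gene_id, normalized_a, normalized_b, ratio,
#'   direction ("up"/"down"/"none"), pass.
#' @export
foldChange <- function(expr, cond_a, cond_b, min_fold = 2, pseudocount = 1) {
  if (!all(c(cond_a, cond_b) %in% expr$condition))
    stop("missing condition: ",
         paste(setdiff(c(cond_a, cond_b), expr$condition), collapse = ", "))
  a <- expr[expr$condition == cond_a, ]
  b <- expr[expr$condition == cond_b, ]
  b <- b[match(a$gene_id, b$gene_id), ]
  ratio <- (a$normalized + pseudocount) / (b$normalized + pseudocount)
  pass <- ratio >= min_fold | ratio <= 1 / min_fold
  data.frame(gene_id = a$gene_id,
             normalized_a = a$normalized, normalized_b = b$normalized,
             ratio = ratio,
             direction = ifelse(!pass, "none",
                                ifelse(ratio >= min_fold, "up", "down")),
             pass = pass, stringsAsFactors = FALSE)
}

#' Rank-based comparison of expression between leader classes
#'
#' Kruskal-Wallis rank test of normalized expression between leadered and
#' leaderless transcripts.
#'
#' @param records UTR record data.frame (gene_id, leader_class).
#' @param expr expression table (one condition's rows, or supply
#'   \code{condition}).
#' @param condition optional condition to subset on.
#' @return the htest object from \code{\link[stats]{kruskal.test}}.
#' @export
leaderExpressionTest <- function(records, expr, condition = NULL) {
  if (!is.null(condition)) expr <- expr[expr$condition == condition, ]
  v <- expr$normalized[match(records$gene_id, expr$gene_id)]
  stats::kruskal.test(v, factor(records$leader_class))
}
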