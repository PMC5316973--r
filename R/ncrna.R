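# Putative ncRNA calling from antisense/intergenic TSSs with promoter
# support, plus GC content and expression-response grouping.

#' GC content of a DNA sequence
#'
#' (G+C) / (A+C+G+T); N is excluded from numerator and denominator.
#'
#' @param sequence character vector of DNA sequences.
#' @return numeric vector of GC fractions.
#' @export
gcContent <- function(sequence) {
  if (any(!nzchar(sequence))) stop("empty sequence")
  vapply(toupper(sequence), function(s) {
    ch <- strsplit(s, "")[[1L]]
    ch <- ch[ch != "N"]
    if (!length(ch)) stop("sequence contains no unambiguous bases")
    mean(ch %in% c("G", "C"))
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Call putative ncRNAs from antisense/intergenic TSSs
#'
#' Every antisense (A) or intergenic (N) TSS whose promoter carries a TATA
#' occurrence overlapping the -30..-20 window becomes a candidate. Its 3'
#' extent is estimated as the maximal downstream run over which coverage
#' stays at or above \code{min_frac} of the TSS-proximal maximum (the peak
#' within the first 20 nt); no experimentally grounded 3'-end rule is
#' available at this scale, so the coverage drop-off rule is a documented
#' stand-in.
#'
#' @param tss classified TSS GRanges.
#' @param tata_occurrences data.frame with tss_id and rel_start
#'   (TSS-relative label of the TATA occurrence start) and width (or a
#'   motif width via \code{tata_width}).
#' @param coverage \linkS4class{CoverageProfile} (ssRNA-seq).
#' @param genome genome sequence.
#' @param tata_width TATA occurrence width when not a column.
#' @param min_frac extent threshold as fraction of the proximal maximum.
#' @param max_extent hard cap on the searched extent in nt.
#' @param tata_window TATA support window (relative labels, inclusive).
#' @return data.frame tss_id, class, position, strand, extent, gc_content,
#'   tata_support, ppe_a (promoter-proximal "A" at -10).
#' @export
callNcRnas <- function(tss, tata_occurrences, coverage, genome,
                       tata_width = 6L, min_frac = 0.1, max_extent = 500L,
                       tata_window = c(-30L, -20L)) {
  g <- .genomeChar(genome)
  L <- nchar(g)
  cand <- tss[tss$category %in% c("A", "N")]
  if (!length(cand))
    return(data.frame(tss_id = character(), class = character(),
                      position = integer(), strand = character(),
                      extent = integer(), gc_content = numeric(),
                      tata_support = logical(), ppe_a = logical(),
                      stringsAsFactors = FALSE))
  occ <- tata_occurrences
  if (!"width" %in% names(occ)) occ$width <- tata_width
  occ_end <- occ$rel_start + occ$width - 1L
  support <- vapply(cand$tss_id, function(id) {
    rows <- which(occ$tss_id == id)
    any(occ$rel_start[rows] <= tata_window[2L] &
        occ_end[rows] >= tata_window[1L])
  }, logical(1L))
  cand <- cand[support]
  if (!length(cand))
    return(data.frame(tss_id = character(), class = character(),
                      position = integer(), strand = character(),
                      extent = integer(), gc_content = numeric(),
                      tata_support = logical(), ppe_a = logical(),
                      stringsAsFactors = FALSE))
  pos <- GenomicRanges::start(cand)
  st <- as.character(GenomicRanges::strand(cand))
  extent <- integer(length(cand))
  gc <- numeric(length(cand))
  ppe <- logical(length(cand))
  for (i in seq_along(cand)) {
    v <- strandSignal(coverage, st[i])
    idx <- if (st[i] == "+") pos[i]:min(pos[i] + max_extent - 1L, L)
           else pos[i]:max(pos[i] - max_extent + 1L, 1L)
    cov <- v[idx]
    peak <- max(cov[seq_len(min(20L, length(cov)))])
    if (peak <= 0) { extent[i] <- 0L } else {
      below <- which(cov < min_frac * peak)
      extent[i] <- if (length(below)) below[1L] - 1L else length(cov)
    }
    if (extent[i] > 0L) {
      span <- idx[seq_len(extent[i])]
      gc[i] <- gcContent(.extractRegion(g, min(span), max(span), st[i]))
    } else gc[i] <- NA_real_
    m10 <- .relToGenomic(pos[i], st[i], -10L)
    ppe[i] <- m10 >= 1L && m10 <= L &&
      .extractRegion(g, m10, m10, st[i]) == "A"
  }
  data.frame(tss_id = cand$tss_id,
             class = ifelse(cand$category == "A", "antisense", "intergenic"),
             position = pos, strand = st, extent = extent,
             gc_content = gc, tata_support = TRUE, ppe_a = ppe,
             stringsAsFactors = FALSE)
}

#' Group ncRNAs by expression response
#'
#' Ratios of normalized expression over the ncRNA extent for each
#' condition pair (vs the reference): candidates with all changed pairs up
#' (ratio >= min_fold, inclusive) form group I, all changed pairs down
#' (<= 1/min_fold) group II; unchanged or discordant candidates stay
#' ungrouped.
#'
#' @param records ncRNA record data.frame from \code{\link{callNcRnas}}.
#' @param profiles named list of \linkS4class{CoverageProfile}s per
#'   condition; the first is the reference.
#' @param min_fold fold threshold (inclusive).
#' @param pseudocount pseudocount on the mean-coverage scale.
#' @return records with per-pair ratio columns and a \code{group} column
#'   ("I", "II" or "none").
#' @export
ncRnaExpressionResponse <- function(records, profiles, min_fold = 2,
                                    pseudocount = 1) {
  if (!nrow(records)) { records$group <- character(0); return(records) }
  conds <- names(profiles)
  ref <- conds[1L]
  meanCov <- function(profile, i) {
    v <- strandSignal(profile, records$strand[i])
    p <- records$position[i]; e <- max(records$extent[i], 1L)
    idx <- if (records$strand[i] == "+") p:(p + e - 1L) else (p - e + 1L):p
    idx <- idx[idx >= 1L & idx <= length(v)]
    mean(v[idx])
  }
  ratios <- matrix(NA_real_, nrow(records), length(conds) - 1L,
                   dimnames = list(NULL, paste0("ratio_", conds[-1L],
                                                "_vs_", ref)))
  for (i in seq_len(nrow(records))) {
    base <- meanCov(profiles[[ref]], i)
    for (j in seq_along(conds[-1L])) {
      x <- meanCov(profiles[[conds[-1L][j]]], i)
      ratios[i, j] <- (x + pseudocount) / (base + pseudocount)
    }
  }
  up <- ratios >= min_fold
  dn <- ratios <= 1 / min_fold
  group <- ifelse(rowSums(up) > 0L & rowSums(dn) == 0L, "I",
                  ifelse(rowSums(dn) > 0L & rowSums(up) == 0L, "II", "none"))
  cbind(records, as.data.frame(ratios), group = group,
        stringsAsFactors = FALSE)
}
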