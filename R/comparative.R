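# Ortholog pairing from precomputed protein hit tables and conservation of
# promoters, 5' UTRs, upstream regions, and ORFs between two genomes.

#' Reciprocal best hits between two proteomes
#'
#' Both hit tables are filtered by E-value and query coverage; the best hit
#' per query is the lowest E-value (ties: highest bit score, then
#' lexicographic subject id). A pair (a, b) is retained iff a's best hit is
#' b and b's best hit is a; the result is a one-to-one matching.
#'
#' @param hits_ab,hits_ba data.frames with columns query_id, subject_id,
#'   e_value, coverage (fraction of the query aligned) and optionally
#'   bit_score.
#' @param e_max E-value threshold (default 1e-10).
#' @param cov_min minimum query coverage (default 0.8).
#' @return data.frame gene_a, gene_b, e_value (of the a->b hit).
#' @export
reciprocalBestPairs <- function(hits_ab, hits_ba, e_max = 1e-10,
                                cov_min = 0.8) {
  prep <- function(h) {
    if (!"bit_score" %in% names(h)) h$bit_score <- 0
    dup <- duplicated(h[, c("query_id", "subject_id")])
    if (any(dup)) {
      warning(sum(dup), " duplicated (query,subject) row(s): keeping best")
      h <- h[order(h$query_id, h$subject_id, h$e_value, -h$bit_score), ]
      h <- h[!duplicated(h[, c("query_id", "subject_id")]), ]
    }
    h <- h[h$e_value <= e_max & h$coverage >= cov_min, , drop = FALSE]
    if (!nrow(h)) return(h[0, ])
    h <- h[order(h$query_id, h$e_value, -h$bit_score, h$subject_id), ]
    h[!duplicated(h$query_id), , drop = FALSE]
  }
  best_ab <- prep(hits_ab)
  best_ba <- prep(hits_ba)
  if (!nrow(best_ab) || !nrow(best_ba))
    return(data.frame(gene_a = character(), gene_b = character(),
                      e_value = numeric(), stringsAsFactors = FALSE))
  back <- stats::setNames(best_ba$subject_id, best_ba$query_id)
  keep <- !is.na(back[best_ab$subject_id]) &
    back[best_ab$subject_id] == best_ab$query_id
  keep[is.na(keep)] <- FALSE
  data.frame(gene_a = best_ab$query_id[keep],
             gene_b = best_ab$subject_id[keep],
             e_value = best_ab$e_value[keep],
             stringsAsFactors = FALSE)
}

#' Global pairwise alignment (Needleman-Wunsch, linear gaps)
#'
#' Deterministic traceback preferring diagonal over up over left on score
#' ties. Percent identity is matches over alignment columns.
#'
#' @param seq_a,seq_b nonempty DNA/character sequences.
#' @param match,mismatch,gap scores (linear gap penalty).
#' @return list(score, identity (percent), alignment (two aligned
#'   strings)).
#' @export
alignPairwise <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("empty sequence")
  M <- matrix(0, n + 1L, m + 1L)
  M[1L, ] <- gap * (0:m)
  M[, 1L] <- gap * (0:n)
  jg <- gap * seq_len(m)
  for (i in seq_len(n)) {
    s <- ifelse(b == a[i], match, mismatch)
    cand <- pmax(M[i, seq_len(m)] + s, M[i, seq_len(m) + 1L] + gap)
    # running max over the left dependency in closed form:
    # M[i+1, j] = max_k<=j (cand_k + (j-k) * gap)
    M[i + 1L, seq_len(m) + 1L] <- jg + cummax(cand - jg)
  }
  # traceback with diagonal > up > left preference
  ai <- character(0); bi <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        M[i + 1L, j + 1L] == M[i, j] +
          (if (a[i] == b[j]) match else mismatch)) {
      ai <- c(a[i], ai); bi <- c(b[j], bi); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && M[i + 1L, j + 1L] == M[i, j + 1L] + gap) {
      ai <- c(a[i], ai); bi <- c("-", bi); i <- i - 1L
    } else {
      ai <- c("-", ai); bi <- c(b[j], bi); j <- j - 1L
    }
  }
  matches <- sum(ai == bi & ai != "-")
  list(score = M[n + 1L, m + 1L],
       identity = 100 * matches / length(ai),
       alignment = c(paste0(ai, collapse = ""), paste0(bi, collapse = "")))
}

# strand-oriented region sequence for one gene in one genome
# region coordinates follow the TSS-relative convention (no position 0)
.regionSeq <- function(region, genome, gene, tsspos, L = .genomeLen(genome)) {
  st <- gene$strand
  cs <- if (st == "+") gene$start else gene$end  # first base of start codon
  switch(region,
    orf = {
      list(lo = gene$start, hi = gene$end, ok = TRUE)
    },
    promoter = {
      r <- sort(c(.relToGenomic(tsspos, st, -40L),
                  .relToGenomic(tsspos, st, -21L)))
      list(lo = r[1L], hi = r[2L], ok = r[1L] >= 1L && r[2L] <= L)
    },
    upstream = {
      r <- sort(c(.relToGenomic(tsspos, st, -100L),
                  .relToGenomic(tsspos, st, -41L)))
      list(lo = r[1L], hi = r[2L], ok = r[1L] >= 1L && r[2L] <= L)
    },
    utr = {
      u <- if (st == "+") cs - tsspos else tsspos - cs
      if (u <= 0L) return(list(lo = NA, hi = NA, ok = FALSE))
      r <- if (st == "+") c(tsspos, cs - 1L) else c(cs + 1L, tsspos)
      list(lo = r[1L], hi = r[2L], ok = r[1L] >= 1L && r[2L] <= L)
    },
    stop("unknown region: ", region))
}

#' Per-region sequence conservation of ortholog pairs
#'
#' For each ortholog pair, the region (\code{orf} = annotated CDS,
#' \code{promoter} = -40..-21 relative to the primary TSS, \code{upstream}
#' = -100..-41, \code{utr} = +1..start codon -1) is extracted
#' strand-oriented from both genomes, globally aligned, and the percent
#' identity recorded; the mean is taken over pairs. Pairs with an
#' undefined or truncated region (e.g. the UTR of a leaderless gene) are
#' skipped and counted.
#'
#' @param pairs data.frame gene_a, gene_b.
#' @param genome_a,genome_b genome sequences.
#' @param annotation_a,annotation_b GRanges annotations.
#' @param tss_a,tss_b data.frames (gene_id, position, strand) giving each
#'   gene's primary TSS.
#' @param region one of "orf", "promoter", "utr", "upstream".
#' @param params alignment scores passed to \code{\link{alignPairwise}}.
#' @return list with \code{per_pair} (data.frame gene_a, gene_b, identity),
#'   \code{mean_identity}, \code{n_skipped}.
#' @export
regionConservation <- function(pairs, genome_a, genome_b,
                               annotation_a, annotation_b, tss_a, tss_b,
                               region = c("orf", "promoter", "utr",
                                          "upstream"),
                               params = list(match = 1, mismatch = -1,
                                             gap = -2)) {
  region <- match.arg(region)
  ga <- .genomeChar(genome_a); gb <- .genomeChar(genome_b)
  La <- nchar(ga); Lb <- nchar(gb)
  annDf <- function(ann) data.frame(
    gene_id = ann$gene_id, start = GenomicRanges::start(ann),
    end = GenomicRanges::end(ann),
    strand = as.character(GenomicRanges::strand(ann)),
    stringsAsFactors = FALSE)
  A <- annDf(annotation_a); B <- annDf(annotation_b)
  res <- list(); skipped <- 0L
  for (k in seq_len(nrow(pairs))) {
    gaRow <- A[A$gene_id == pairs$gene_a[k], ]
    gbRow <- B[B$gene_id == pairs$gene_b[k], ]
    ta <- tss_a$position[tss_a$gene_id == pairs$gene_a[k]][1L]
    tb <- tss_b$position[tss_b$gene_id == pairs$gene_b[k]][1L]
    if (!nrow(gaRow) || !nrow(gbRow) ||
        (region != "orf" && (is.na(ta) || is.na(tb) ||
                             !length(ta) || !length(tb)))) {
      skipped <- skipped + 1L; next
    }
    ra <- .regionSeq(region, ga, gaRow[1L, ], ta, La)
    rb <- .regionSeq(region, gb, gbRow[1L, ], tb, Lb)
    if (!isTRUE(ra$ok) || !isTRUE(rb$ok)) { skipped <- skipped + 1L; next }
    sa <- .extractRegion(ga, ra$lo, ra$hi, gaRow$strand[1L])
    sb <- .extractRegion(gb, rb$lo, rb$hi, gbRow$strand[1L])
    al <- alignPairwise(sa, sb, params$match, params$mismatch, params$gap)
    res[[length(res) + 1L]] <- data.frame(
      gene_a = pairs$gene_a[k], gene_b = pairs$gene_b[k],
      identity = al$identity, stringsAsFactors = FALSE)
  }
  per_pair <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_a = character(), gene_b = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  list(per_pair = per_pair,
       mean_identity = if (nrow(per_pair)) mean(per_pair$identity)
                       else NA_real_,
       n_skipped = skipped)
}

#' Correlation of 5' UTR lengths across ortholog pairs
#'
#' @param utr_a,utr_b paired UTR lengths (nt), same length >= 3.
#' @return list(r_squared, n, n_identical, pct_identical).
#' @export
utrLengthCorrelation <- function(utr_a, utr_b) {
  ok <- !is.na(utr_a) & !is.na(utr_b)
  utr_a <- utr_a[ok]; utr_b <- utr_b[ok]
  if (length(utr_a) < 3L) stop("need at least 3 pairs with defined UTRs")
  r2 <- stats::cor(utr_a, utr_b)^2
  ident <- sum(utr_a == utr_b)
  list(r_squared = r2, n = length(utr_a), n_identical = ident,
       pct_identical = 100 * ident / length(utr_a))
}
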