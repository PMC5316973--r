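# 5' UTR lengths, leadered/leaderless classification, and summaries.

#' 5' UTR length of a primary TSS relative to its gene
#'
#' On the forward strand the UTR length is gene start minus TSS position;
#' on the reverse strand it is TSS position minus gene end (the gene end is
#' the genomic coordinate of the first base of the start codon). A negative
#' value means the TSS lies downstream of the start codon; such records are
#' excluded from UTR statistics by callers.
#'
#' @param tss_position 1-based TSS position.
#' @param tss_strand "+" or "-".
#' @param gene_start,gene_end 1-based inclusive gene coordinates.
#' @param gene_strand gene strand; must equal the TSS strand.
#' @return signed UTR length in nt.
#' @export
computeUtr <- function(tss_position, tss_strand, gene_start, gene_end,
                       gene_strand) {
  if (any(tss_strand != gene_strand))
    stop("TSS and gene must be on the same strand")
  ifelse(tss_strand == "+", gene_start - tss_position,
         tss_position - gene_end)
}

#' Leadered / leaderless classification of a UTR length
#'
#' A transcript is leaderless (lmRNA) iff its 5' UTR length is at most the
#' threshold (default 5 nt, inclusive -- the ~6 nt needed by a consensus
#' ribosome-binding site does not fit); otherwise leadered (umRNA).
#'
#' @param utr_length non-negative UTR length(s) in nt.
#' @param threshold inclusive lmRNA threshold in nt.
#' @return character vector, \code{"lmRNA"} or \code{"umRNA"}.
#' @export
classifyLeader <- function(utr_length, threshold = 5L) {
  if (any(utr_length < 0L)) stop("negative UTR length")
  ifelse(utr_length <= threshold, "lmRNA", "umRNA")
}

#' Build the UTR record table from classified TSSs
#'
#' One record per primary TSS linked to a protein-coding gene with a
#' non-negative UTR; TSSs downstream of the start codon are flagged and
#' excluded (a negative UTR is undefined).
#'
#' @param tss classified TSS GRanges.
#' @param annotation GRanges annotation.
#' @param genome genome (DNAStringSet or character) for start codons.
#' @param threshold inclusive lmRNA threshold in nt.
#' @return data.frame with tss_id, gene_id, utr_length, leader_class,
#'   start_codon.
#' @export
utrTable <- function(tss, annotation, genome, threshold = 5L) {
  p <- tss[tss$category == "P" & !is.na(tss$gene_id)]
  kind <- stats::setNames(annotation$feature_kind, annotation$gene_id)
  p <- p[kind[p$gene_id] == "CDS"]
  if (!length(p))
    return(data.frame(tss_id = character(), gene_id = character(),
                      utr_length = integer(), leader_class = character(),
                      start_codon = character(), stringsAsFactors = FALSE))
  idx <- match(p$gene_id, annotation$gene_id)
  utr <- computeUtr(GenomicRanges::start(p),
                    as.character(GenomicRanges::strand(p)),
                    GenomicRanges::start(annotation)[idx],
                    GenomicRanges::end(annotation)[idx],
                    as.character(GenomicRanges::strand(annotation))[idx])
  ok <- utr >= 0L
  p <- p[ok]; idx <- idx[ok]; utr <- utr[ok]
  codon <- startCodon(annotation[idx], genome)
  data.frame(tss_id = p$tss_id, gene_id = p$gene_id,
             utr_length = as.integer(utr),
             leader_class = classifyLeader(utr, threshold),
             start_codon = codon, stringsAsFactors = FALSE)
}

#' Annotated start codons read from the genome
#'
#' @param annotation GRanges of genes.
#' @param genome genome sequence.
#' @return character vector of strand-oriented start trinucleotides.
#' @export
startCodon <- function(annotation, genome) {
  g <- .genomeChar(genome)
  st <- as.character(GenomicRanges::strand(annotation))
  s <- GenomicRanges::start(annotation)
  e <- GenomicRanges::end(annotation)
  vapply(seq_along(annotation), function(i) {
    if (st[i] == "+") substr(g, s[i], s[i] + 2L)
    else .revcomp(substr(g, e[i] - 2L, e[i]))
  }, character(1L))
}

#' UTR length distribution summary
#'
#' Histogram at 1-nt resolution, median (lower-median convention for even
#' n), maximum, and the fraction of UTRs of 0--50 nt.
#'
#' @param utr_lengths non-negative integer vector (one per record).
#' @return list(histogram, median, max, fraction_0_50, n).
#' @export
utrLengthDistribution <- function(utr_lengths) {
  if (!length(utr_lengths)) stop("empty UTR record set")
  utr_lengths <- as.integer(utr_lengths)
  h <- table(factor(utr_lengths, levels = 0:max(utr_lengths)))
  s <- sort(utr_lengths)
  med <- s[ceiling(length(s) / 2)]  # lower median for even n
  list(histogram = h,
       median = med,
       max = max(utr_lengths),
       fraction_0_50 = 100 * mean(utr_lengths <= 50L),
       n = length(utr_lengths))
}

#' COG functional summary per leader class
#'
#' Counts per COG letter for leadered and leaderless records; genes whose
#' annotation carries no COG letter are counted as unassigned. Multi-letter
#' assignments count once under the first letter.
#'
#' @param records UTR record data.frame (gene_id, leader_class).
#' @param annotation GRanges with a cog_category mcol.
#' @return list with \code{counts} (table class x letter), \code{assigned},
#'   \code{unassigned}, \code{pct_assigned} per class, \code{n} per class.
#' @export
cogSummary <- function(records, annotation) {
  cog <- stats::setNames(annotation$cog_category, annotation$gene_id)
  letter <- substr(cog[records$gene_id], 1L, 1L)
  letter[letter %in% c("", "-")] <- NA_character_
  cls <- factor(records$leader_class, levels = c("umRNA", "lmRNA"))
  assigned <- tapply(!is.na(letter), cls, sum, default = 0L)
  n <- tapply(rep(1L, length(cls)), cls, sum, default = 0L)
  counts <- table(cls[!is.na(letter)], letter[!is.na(letter)])
  list(counts = counts,
       assigned = assigned,
       unassigned = n - assigned,
       pct_assigned = 100 * assigned / pmax(n, 1L),
       n = n)
}

#' Start codon usage per leader class
#'
#' @param records UTR record data.frame (start_codon, leader_class).
#' @return matrix of fractions (rows: ATG, GTG, TTG, other; columns:
#'   leader classes), each column summing to 1.
#' @export
startCodonUsage <- function(records) {
  codon <- records$start_codon
  codon[!codon %in% c("ATG", "GTG", "TTG")] <- "other"
  cls <- factor(records$leader_class, levels = c("umRNA", "lmRNA"))
  tab <- table(factor(codon, levels = c("ATG", "GTG", "TTG", "other")), cls)
  prop.table(tab, margin = 2L)
}
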