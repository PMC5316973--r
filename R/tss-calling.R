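# TSS detection, iterative cluster subdivision, and five-way classification.
#
# The calling rules, in order:
#   1. every genomic position with >= 1 TEX+ 5'-end read is a potential TSS;
#      it is retained only if the TEX- library has a 5' end within +/- 5 nt
#      on the same strand (cross-library confirmation);
#   2. retained candidates within 150 nt of each other (single-linkage) form
#      a cluster; clusters are recursively subdivided at the largest
#      inter-member gap until the count-weighted positional SD is < 15 nt;
#   3. sub-clusters totalling fewer than 3 reads are dropped; otherwise the
#      member with the most reads is the TSS (tie: 5'-most);
#   4. adjacent TSSs from one original cluster whose pairwise weighted SD is
#      < 15 nt are merged by dropping the lower-read one;
#   5. TSSs are classified P/S/I/A/N against the annotation, and secondary /
#      internal TSSs with fewer than 50% of the reads of the relevant
#      primary TSS are dropped.

#' Parameters of the TSS calling procedure
#'
#' @param cross_library_window nt tolerance for TEX- confirmation (+/- 5).
#' @param cluster_gap single-linkage clustering distance in nt (150).
#' @param sd_threshold weighted positional SD below which a (sub)cluster is
#'   considered a single TSS signal (15 nt).
#' @param min_reads minimum total reads of a retained sub-cluster (3).
#' @param upstream_window,downstream_window P/S classification window
#'   relative to the start codon (-300..+50).
#' @param secondary_min_ratio minimum read fraction, relative to the primary
#'   TSS, for retaining secondary/internal TSSs (0.5).
#' @return validated list of class \code{"CallingParams"}.
#' @export
callingParams <- function(cross_library_window = 5L,
                          cluster_gap = 150L,
                          sd_threshold = 15,
                          min_reads = 3L,
                          upstream_window = 300L,
                          downstream_window = 50L,
                          secondary_min_ratio = 0.5) {
  p <- list(cross_library_window = as.integer(cross_library_window),
            cluster_gap = as.integer(cluster_gap),
            sd_threshold = sd_threshold,
            min_reads = as.integer(min_reads),
            upstream_window = as.integer(upstream_window),
            downstream_window = as.integer(downstream_window),
            secondary_min_ratio = secondary_min_ratio)
  stopifnot(p$cross_library_window >= 0L, p$cluster_gap > 0L,
            p$sd_threshold > 0, p$min_reads > 0L,
            p$upstream_window > 0L, p$downstream_window >= 0L,
            p$secondary_min_ratio > 0, p$secondary_min_ratio <= 1)
  class(p) <- "CallingParams"
  p
}

#' Detect TSS candidates by cross-library confirmation
#'
#' A position with at least one TEX+ 5'-end read is a candidate iff the
#' TEX- profile has a nonzero 5'-end count within the cross-library window
#' on the same strand.
#'
#' @param texPlus,texMinus \linkS4class{FivePrimeProfile}s of the TEX+
#'   and TEX- libraries (same genome).
#' @param params \code{\link{callingParams}}.
#' @return data.frame with columns position, strand, count.
#' @export
detectCandidates <- function(texPlus, texMinus, params = callingParams()) {
  stopifnot(libraryKind(texPlus) == "TEX_PLUS",
            libraryKind(texMinus) == "TEX_MINUS",
            profileLength(texPlus) == profileLength(texMinus))
  w <- params$cross_library_window
  one <- function(strand) {
    plus <- strandSignal(texPlus, strand)
    minus <- strandSignal(texMinus, strand)
    pos <- which(plus > 0L)
    if (!length(pos)) return(NULL)
    cs <- cumsum(c(0L, minus > 0L))
    L <- length(minus)
    lo <- pmax(pos - w, 1L); hi <- pmin(pos + w, L)
    supported <- (cs[hi + 1L] - cs[lo]) > 0L
    pos <- pos[supported]
    if (!length(pos)) return(NULL)
    data.frame(position = pos, strand = strand, count = plus[pos],
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("+"), one("-"))
  if (is.null(out))
    out <- data.frame(position = integer(), strand = character(),
                      count = integer(), stringsAsFactors = FALSE)
  out
}

#' Cluster candidates on one strand by single-linkage chaining
#'
#' Two candidates belong to one cluster iff a chain of pairwise gaps each
#' <= cluster_gap connects them.
#'
#' @param candidates data.frame (position, count) on a single strand.
#' @param params \code{\link{callingParams}}.
#' @return list of clusters, each a list(positions, counts).
#' @export
clusterCandidates <- function(candidates, params = callingParams()) {
  if (!nrow(candidates)) return(list())
  if ("strand" %in% names(candidates) &&
      length(unique(candidates$strand)) > 1L)
    stop("clusterCandidates expects candidates from a single strand")
  ord <- order(candidates$position)
  pos <- candidates$position[ord]
  cnt <- candidates$count[ord]
  brk <- cumsum(c(1L, as.integer(diff(pos) > params$cluster_gap)))
  lapply(split(seq_along(pos), brk), function(i)
    list(positions = pos[i], counts = cnt[i]))
}

#' Recursively subdivide a cluster until its weighted SD is below threshold
#'
#' If the count-weighted positional SD of the cluster is below the
#' threshold it is returned unchanged; otherwise the members are split at
#' the single largest inter-member gap (ties: leftmost gap) and both halves
#' are subdivided recursively. Each split strictly reduces the member
#' count, so the recursion terminates.
#'
#' @param cluster list(positions, counts), positions sorted ascending.
#' @param params \code{\link{callingParams}}.
#' @return list of sub-clusters in positional order.
#' @export
subdivideCluster <- function(cluster, params = callingParams()) {
  pos <- cluster$positions; cnt <- cluster$counts
  if (length(pos) <= 1L ||
      weightedSd(pos, cnt) < params$sd_threshold)
    return(list(cluster))
  gaps <- diff(pos)
  cut <- which.max(gaps)   # leftmost maximal gap
  left <- list(positions = pos[seq_len(cut)], counts = cnt[seq_len(cut)])
  right <- list(positions = pos[-seq_len(cut)], counts = cnt[-seq_len(cut)])
  c(subdivideCluster(left, params), subdivideCluster(right, params))
}

#' Select the TSS of a sub-cluster
#'
#' Sub-clusters with fewer than \code{min_reads} total reads yield no TSS;
#' otherwise the member with the most reads is selected (tie: 5'-most
#' position relative to the strand).
#'
#' @param subcluster list(positions, counts).
#' @param strand "+" or "-" (decides the 5'-most tie-break direction).
#' @param params \code{\link{callingParams}}.
#' @return list(position, count) or NULL.
#' @export
selectTss <- function(subcluster, strand = "+", params = callingParams()) {
  pos <- subcluster$positions; cnt <- subcluster$counts
  if (sum(cnt) < params$min_reads) return(NULL)
  best <- which(cnt == max(cnt))
  if (length(best) > 1L) {
    best <- if (strand == "+") best[which.min(pos[best])]
            else best[which.max(pos[best])]
  }
  list(position = pos[best], count = cnt[best])
}

#' Merge adjacent TSSs within one original cluster
#'
#' For each adjacent pair of TSSs the count-weighted positional SD is
#' computed; if it falls below the threshold, the lower-read TSS is removed
#' (tie: the downstream one). The scan repeats until stable.
#'
#' @param tss_list data.frame (position, count) from one cluster, sorted by
#'   position.
#' @param strand "+" or "-".
#' @param params \code{\link{callingParams}}.
#' @return data.frame (position, count) of surviving TSSs.
#' @export
mergeAdjacentTss <- function(tss_list, strand = "+",
                             params = callingParams()) {
  if (!nrow(tss_list)) return(tss_list)
  tss_list <- tss_list[order(tss_list$position), , drop = FALSE]
  repeat {
    if (nrow(tss_list) < 2L) break
    dropped <- FALSE
    for (i in seq_len(nrow(tss_list) - 1L)) {
      pr <- tss_list[i:(i + 1L), ]
      sdv <- weightedSd(pr$position, pr$count)
      if (sdv < params$sd_threshold) {
        if (pr$count[1L] == pr$count[2L]) {
          # tie: drop the downstream TSS
          drop_row <- if (strand == "+") i + 1L else i
        } else {
          drop_row <- i - 1L + which.min(pr$count)
        }
        tss_list <- tss_list[-drop_row, , drop = FALSE]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  rownames(tss_list) <- NULL
  tss_list
}

# run cluster -> subdivide -> select -> merge on one strand's candidates
.callStrand <- function(candidates, strand, params) {
  clusters <- clusterCandidates(candidates, params)
  out <- list()
  for (cl in clusters) {
    subs <- subdivideCluster(cl, params)
    sel <- lapply(subs, selectTss, strand = strand, params = params)
    sel <- sel[!vapply(sel, is.null, logical(1L))]
    if (!length(sel)) next
    df <- data.frame(position = vapply(sel, `[[`, numeric(1L), "position"),
                     count = vapply(sel, `[[`, numeric(1L), "count"))
    out[[length(out) + 1L]] <- mergeAdjacentTss(df, strand, params)
  }
  if (!length(out))
    return(data.frame(position = integer(), count = integer()))
  res <- do.call(rbind, out)
  res[order(res$position), , drop = FALSE]
}

#' Classify curated TSSs against a gene annotation
#'
#' For each ORF, TSSs on its strand with a start-codon distance in
#' [-upstream_window, +downstream_window] compete: the max-read TSS is
#' primary (P), the others secondary (S). TSSs not claimed as P/S that fall
#' inside an annotated ORF are internal (I, same strand) or antisense (A,
#' opposite strand); the remainder are intergenic (N). Secondary and
#' internal TSSs with fewer than \code{secondary_min_ratio} of the relevant
#' primary TSS's reads are dropped. A TSS eligible for several ORFs is
#' assigned to the ORF with the nearest downstream start codon on its
#' strand.
#'
#' @param tss data.frame (position, strand, count) of curated TSSs.
#' @param annotation GRanges with gene_id/feature_kind mcols.
#' @param params \code{\link{callingParams}}.
#' @param seqname chromosome name for the returned GRanges.
#' @return GRanges of width-1 TSSs with mcols tss_id, read_count, category,
#'   gene_id, distance_to_start.
#' @export
classifyTss <- function(tss, annotation, params = callingParams(),
                        seqname = "genome") {
  if (any(as.character(GenomicRanges::strand(annotation)) == "*"))
    stop("annotation without strand")
  ann <- data.frame(
    gene_id = annotation$gene_id,
    start = GenomicRanges::start(annotation),
    end = GenomicRanges::end(annotation),
    strand = as.character(GenomicRanges::strand(annotation)),
    stringsAsFactors = FALSE)
  n <- nrow(tss)
  category <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)

  # distance_to_start: negative upstream of the start codon
  distTo <- function(pos, strand, gstart, gend) {
    if (strand == "+") pos - gstart else gend - pos
  }

  # assign each TSS to at most one ORF within the classification window
  for (i in seq_len(n)) {
    same <- ann[ann$strand == tss$strand[i], , drop = FALSE]
    if (!nrow(same)) next
    d <- distTo(tss$position[i], tss$strand[i], same$start, same$end)
    elig <- which(d >= -params$upstream_window &
                  d <= params$downstream_window)
    if (!length(elig)) next
    # nearest downstream start codon: smallest non-negative (start codon
    # downstream of the TSS => d <= 0 here); fall back to smallest |d|
    dd <- d[elig]
    down <- which(dd <= 0L)
    pick <- if (length(down)) elig[down[which.max(dd[down])]]
            else elig[which.min(abs(dd))]
    gene_id[i] <- same$gene_id[pick]
    dist[i] <- d[pick]
  }

  # per ORF: max-read TSS is primary, the rest secondary
  claimed <- !is.na(gene_id)
  for (gid in unique(gene_id[claimed])) {
    idx <- which(gene_id == gid)
    cnt <- tss$count[idx]
    best <- idx[which(cnt == max(cnt))]
    if (length(best) > 1L) {
      # tie: 5'-most position wins
      p <- tss$position[best]
      best <- if (tss$strand[best[1L]] == "+") best[which.min(p)]
              else best[which.max(p)]
    }
    category[best] <- "P"
    category[setdiff(idx, best)] <- "S"
  }

  # remaining TSSs: internal / antisense / intergenic
  unclaimed <- which(is.na(category))
  for (i in unclaimed) {
    inside <- ann$start <= tss$position[i] & ann$end >= tss$position[i]
    if (any(inside & ann$strand == tss$strand[i])) {
      category[i] <- "I"
      gid <- ann$gene_id[inside & ann$strand == tss$strand[i]][1L]
      gene_id[i] <- gid
    } else if (any(inside)) {
      category[i] <- "A"
    } else {
      category[i] <- "N"
    }
  }

  # drop S and I with fewer than secondary_min_ratio of the relevant primary
  primary_count <- stats::setNames(tss$count[category == "P"],
                                   gene_id[category == "P"])
  keep <- rep(TRUE, n)
  for (i in which(category %in% c("S", "I"))) {
    gid <- gene_id[i]
    if (is.na(gid) || !gid %in% names(primary_count)) next
    if (tss$count[i] < params$secondary_min_ratio * primary_count[[gid]])
      keep[i] <- FALSE
  }

  tss <- tss[keep, , drop = FALSE]
  category <- category[keep]; gene_id <- gene_id[keep]; dist <- dist[keep]
  gene_id[category %in% c("A", "N")] <- NA_character_
  dist[!category %in% c("P", "S")] <- NA_integer_

  ord <- order(tss$position)
  gr <- GenomicRanges::GRanges(
    seqname, IRanges::IRanges(tss$position[ord], width = 1L),
    strand = tss$strand[ord])
  S4Vectors::mcols(gr)$tss_id <- sprintf("TSS%04d", seq_along(gr))
  S4Vectors::mcols(gr)$read_count <- tss$count[ord]
  S4Vectors::mcols(gr)$category <- category[ord]
  S4Vectors::mcols(gr)$gene_id <- gene_id[ord]
  S4Vectors::mcols(gr)$distance_to_start <- dist[ord]
  gr
}

#' Full TSS calling pipeline
#'
#' Runs candidate detection, per-strand clustering/subdivision/selection/
#' merging, and classification.
#'
#' @param texPlus,texMinus \linkS4class{FivePrimeProfile}s.
#' @param annotation GRanges annotation.
#' @param params \code{\link{callingParams}}.
#' @param seqname chromosome name for the output.
#' @return classified TSS GRanges (see \code{\link{classifyTss}}).
#' @export
callTss <- function(texPlus, texMinus, annotation,
                    params = callingParams(), seqname = "genome") {
  cand <- detectCandidates(texPlus, texMinus, params)
  curated <- list()
  for (st in c("+", "-")) {
    cc <- cand[cand$strand == st, , drop = FALSE]
    res <- .callStrand(cc, st, params)
    if (nrow(res)) {
      res$strand <- st
      curated[[st]] <- res
    }
  }
  curated <- if (length(curated)) do.call(rbind, curated)
             else data.frame(position = integer(), count = integer(),
                             strand = character())
  rownames(curated) <- NULL
  classifyTss(curated, annotation, params, seqname)
}

#' Map operons to their primary TSSs
#'
#' An operon is TSS-determined iff its first gene (5'-most member on the
#' operon strand) has a primary TSS.
#'
#' @param tss classified TSS GRanges (only category "P" rows are used).
#' @param operons data.frame with columns operon_id, gene_id (and
#'   optionally pos_in_operon giving the 5'->3' member order).
#' @param annotation GRanges annotation (used to order members when
#'   pos_in_operon is absent and to validate membership).
#' @return list with \code{mapping} (data.frame operon_id, first_gene,
#'   tss_id, determined) and \code{summary} (counts and percentages of
#'   determined operons overall / single-gene / multi-gene).
#' @export
assignOperonTss <- function(tss, operons, annotation) {
  unknown <- setdiff(operons$gene_id, annotation$gene_id)
  if (length(unknown))
    stop("operon references unknown gene(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  ann_start <- stats::setNames(GenomicRanges::start(annotation),
                               annotation$gene_id)
  ann_end <- stats::setNames(GenomicRanges::end(annotation),
                             annotation$gene_id)
  ann_strand <- stats::setNames(as.character(GenomicRanges::strand(annotation)),
                                annotation$gene_id)
  p <- tss[tss$category == "P"]
  p_by_gene <- stats::setNames(p$tss_id, p$gene_id)

  ops <- split(operons, operons$operon_id)
  mapping <- do.call(rbind, lapply(ops, function(o) {
    st <- ann_strand[o$gene_id[1L]]
    first <- if ("pos_in_operon" %in% names(o) && !anyNA(o$pos_in_operon)) {
      o$gene_id[which.min(o$pos_in_operon)]
    } else if (st == "+") {
      o$gene_id[which.min(ann_start[o$gene_id])]
    } else {
      o$gene_id[which.max(ann_end[o$gene_id])]
    }
    tid <- if (first %in% names(p_by_gene)) p_by_gene[[first]] else NA_character_
    data.frame(operon_id = o$operon_id[1L], first_gene = first,
               n_genes = nrow(o), tss_id = tid,
               determined = !is.na(tid), stringsAsFactors = FALSE)
  }))
  rownames(mapping) <- NULL
  multi <- mapping$n_genes >= 2L
  summary <- list(
    n_operons = nrow(mapping),
    n_determined = sum(mapping$determined),
    pct_determined = 100 * sum(mapping$determined) / nrow(mapping),
    n_multi = sum(multi),
    n_multi_determined = sum(mapping$determined & multi),
    pct_multi_determined = if (any(multi))
      100 * sum(mapping$determined & multi) / sum(multi) else NA_real_,
    n_single = sum(!multi),
    n_single_determined = sum(mapping$determined & !multi))
  list(mapping = mapping, summary = summary)
}
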