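# Promoter element discovery and degenerate motif scanning.
#
# Positions relative to a TSS skip 0: +1 is the TSS base, -1 the base
# immediately 5' of it. Motif discovery is a single-motif ZOOPS (zero or
# one occurrence per sequence) expectation-maximization over a 0-order
# background, seeded deterministically; it recovers motif localization and
# consensus, not statistical significance.

#' Extract fixed promoter windows around TSSs
#'
#' Strand-oriented windows covering \code{-upstream..-1, +1..+downstream}
#' relative to each TSS (+1 = TSS base); for reverse-strand TSSs the
#' reverse complement is returned so upstream is always leftward. Windows
#' truncated by the genome boundary are flagged.
#'
#' @param tss classified TSS GRanges (or any width-1 GRanges with a
#'   tss_id mcol).
#' @param genome genome sequence.
#' @param upstream,downstream window extents in nt (default -50..+10).
#' @return data.frame with tss_id, position, strand, sequence, truncated.
#' @export
promoterWindows <- function(tss, genome, upstream = 50L, downstream = 10L) {
  g <- .genomeChar(genome)
  L <- nchar(g)
  pos <- GenomicRanges::start(tss)
  if (any(pos < 1L | pos > L)) stop("TSS outside genome")
  st <- as.character(GenomicRanges::strand(tss))
  lo <- ifelse(st == "+", pos - upstream, pos - downstream + 1L)
  hi <- ifelse(st == "+", pos + downstream - 1L, pos + upstream)
  truncated <- lo < 1L | hi > L
  lo <- pmax(lo, 1L); hi <- pmin(hi, L)
  seqs <- substring(g, lo, hi)
  seqs[st == "-"] <- .revcomp(seqs[st == "-"])
  ids <- if (!is.null(tss$tss_id)) tss$tss_id else
    sprintf("TSS%04d", seq_along(tss))
  data.frame(tss_id = ids, position = pos, strand = st,
             sequence = seqs, truncated = truncated,
             stringsAsFactors = FALSE)
}

# IUPAC letter for a set of bases
.iupacFromSet <- function(bases) {
  hit <- vapply(.IUPAC, function(s)
    length(s) == length(bases) && all(sort(s) == sort(bases)), logical(1L))
  names(.IUPAC)[hit][1L]
}

# IUPAC consensus of a frequency matrix: smallest high-frequency base set
# reaching 80% of the column mass
.consensusIupac <- function(freq) {
  paste0(apply(freq, 2L, function(f) {
    ord <- order(f, decreasing = TRUE)
    k <- which(cumsum(f[ord]) >= 0.8)[1L]
    .iupacFromSet(rownames(freq)[sort(ord[seq_len(k)])])
  }), collapse = "")
}

# per-column information content in bits against a uniform background
.infoContent <- function(freq) {
  apply(freq, 2L, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
}

#' Discover a single fixed-width motif by ZOOPS expectation-maximization
#'
#' Each sequence contributes zero or one motif occurrence. The E-step
#' computes per-offset occurrence posteriors from the current frequency
#' matrix against a 0-order background estimated from the input; the
#' M-step re-estimates the matrix with pseudocounts and the occurrence
#' prior. Several seeded restarts are run and the highest-likelihood model
#' returned; results are deterministic given the seed.
#'
#' @param sequences character vector of equal-length DNA windows (>= 10).
#' @param width motif width in nt (<= window length).
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts number of seeded restarts.
#' @param pseudocount pseudocount per matrix cell.
#' @param seed integer seed.
#' @return list with \code{model} (a \linkS4class{MotifModel}) and
#'   \code{occurrences} (data.frame seq_index, offset0, posterior, score
#'   in log-odds bits; one row per sequence with occurrence posterior >=
#'   0.5, offset0 0-based within the window).
#' @export
discoverMotif <- function(sequences, width, max_iter = 100L,
                          n_restarts = 5L, pseudocount = 0.25, seed = 1L) {
  n <- length(sequences)
  if (n < 10L) stop("motif discovery needs at least 10 windows")
  W <- unique(nchar(sequences))
  if (length(W) != 1L) stop("windows must have equal length")
  if (width > W) stop("width exceeds window length")
  m <- W - width + 1L

  X <- matrix(match(unlist(strsplit(sequences, "")), .BASES),
              nrow = n, byrow = TRUE)
  if (anyNA(X)) stop("windows must contain only A/C/G/T")
  bg <- tabulate(X, 4L) / length(X)
  bg[bg == 0] <- 1e-9
  logbg <- log(bg)
  # per-offset slices of the window matrix
  slices <- lapply(seq_len(m), function(j) X[, j:(j + width - 1L), drop = FALSE])
  logbg_slice <- vapply(slices, function(s)
    rowSums(matrix(logbg[s], nrow = n)), numeric(n))
  if (is.null(dim(logbg_slice))) logbg_slice <- matrix(logbg_slice, nrow = n)

  scoreAll <- function(logf) {
    # n x m matrix of log motif/background ratios
    sc <- matrix(0, n, m)
    for (j in seq_len(m)) {
      s <- slices[[j]]
      acc <- numeric(n)
      for (k in seq_len(width)) acc <- acc + logf[s[, k], k]
      sc[, j] <- acc - logbg_slice[, j]
    }
    sc
  }

  runEM <- function(counts, gamma) {
    f <- sweep(counts, 2L, colSums(counts), "/")
    ll_prev <- -Inf
    ll_trace <- numeric(0)
    z <- NULL; sc <- NULL
    for (it in seq_len(max_iter)) {
      sc <- scoreAll(log(f))
      rowmax <- apply(sc, 1L, max)
      e <- exp(sc - rowmax)
      # log((1-gamma) + (gamma/m) * sum_j exp(sc_ij)); the whole-window
      # background likelihood is a constant and omitted
      denom_log <- rowmax + log((1 - gamma) * exp(-rowmax) +
                                (gamma / m) * rowSums(e))
      z <- (gamma / m) * exp(sc - denom_log)
      ll <- sum(denom_log)
      ll_trace <- c(ll_trace, ll)
      # M-step: for motif column k, offsets j sweep window columns k..k+m-1
      counts <- matrix(pseudocount, 4L, width)
      for (k in seq_len(width)) {
        Xk <- X[, k:(k + m - 1L), drop = FALSE]
        for (b in 1:4) counts[b, k] <- counts[b, k] + sum(z[Xk == b])
      }
      f <- sweep(counts, 2L, colSums(counts), "/")
      gamma <- min(max(mean(rowSums(z)), 1e-3), 0.999)
      if (is.finite(ll_prev) && ll - ll_prev < 1e-6) { ll_prev <- ll; break }
      ll_prev <- ll
    }
    list(f = f, counts = counts, gamma = gamma, ll = ll_prev, z = z,
         sc = sc, trace = ll_trace)
  }

  # hard-assignment counts from per-window offsets (for seeding)
  countsFromOffsets <- function(idx, off) {
    counts <- matrix(pseudocount + 0.5, 4L, width)
    for (t in seq_along(idx)) {
      word <- X[idx[t], off[t]:(off[t] + width - 1L)]
      counts[cbind(word, seq_len(width))] <-
        counts[cbind(word, seq_len(width))] + 1
    }
    counts
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    i0 <- sample.int(n, 1L); j0 <- sample.int(m, 1L)
    counts <- matrix(pseudocount + 0.5, 4L, width)
    seedword <- X[i0, j0:(j0 + width - 1L)]
    counts[cbind(seedword, seq_len(width))] <-
      counts[cbind(seedword, seq_len(width))] + 4
    res <- runEM(counts, 0.5)
    if (is.null(best) || res$ll > best$ll) best <- res
  }

  # phase-shift refinement: re-seed from the current occurrence register
  # shifted by a few columns and keep any strictly better solution
  for (pass in 1:4) {
    improved <- FALSE
    occ_p <- rowSums(best$z)
    off <- max.col(best$z, ties.method = "first")
    use <- occ_p >= 0.5
    for (s in c(-2L, -1L, 1L, 2L)) {
      off_s <- off + s
      ok <- use & off_s >= 1L & off_s <= m
      if (sum(ok) < 10L) next
      res <- runEM(countsFromOffsets(which(ok), off_s[ok]), best$gamma)
      if (res$ll > best$ll + 1e-9) { best <- res; improved <- TRUE; break }
    }
    if (!improved) break
  }

  rownames(best$f) <- rownames(best$counts) <- .BASES
  model <- methods::new("MotifModel",
    width = as.integer(width), counts = best$counts, freq = best$f,
    pseudocount = pseudocount, background = bg,
    consensus = .consensusIupac(best$f),
    information = pmin(pmax(.infoContent(best$f), 0), 2),
    logLik = best$ll, gamma = best$gamma)

  occ_prob <- rowSums(best$z)
  has <- occ_prob >= 0.5
  off <- max.col(best$z, ties.method = "first") - 1L
  occurrences <- data.frame(
    seq_index = which(has),
    offset0 = off[has],
    posterior = occ_prob[has],
    score = best$sc[cbind(which(has), off[has] + 1L)] / log(2))
  list(model = model, occurrences = occurrences, logLik_trace = best$trace)
}

#' Map a 0-based window offset to a TSS-relative position label
#'
#' @param offset0 0-based offset within a window extracted with
#'   \code{\link{promoterWindows}}.
#' @param upstream the window's upstream extent.
#' @param downstream the window's downstream extent.
#' @return signed position label (0 skipped).
#' @export
offsetToRelative <- function(offset0, upstream, downstream = 10L) {
  windowPositions(upstream, downstream)[offset0 + 1L]
}

#' Re-extract fixed flanks around located motif occurrences
#'
#' For each occurrence (genomic TSS position, strand, and TSS-relative
#' start label of the motif), extracts \code{up} nt upstream of the first
#' motif base and \code{down} nt downstream of the last, yielding an
#' aligned block of width up + motif width + down for logo rendering and
#' flank inspection. Occurrences with truncated flanks are dropped.
#'
#' @param occurrences data.frame with columns position (TSS genomic
#'   position), strand, rel_start (TSS-relative label of the motif start).
#' @param genome genome sequence.
#' @param width motif width in nt.
#' @param up,down flank extents in nt.
#' @return character vector of aligned block sequences (named by row).
#' @export
realignMotifWindow <- function(occurrences, genome, width,
                               up = 7L, down = 21L) {
  g <- .genomeChar(genome)
  L <- nchar(g)
  out <- character(0)
  for (i in seq_len(nrow(occurrences))) {
    p <- occurrences$position[i]; st <- occurrences$strand[i]
    labs <- .relLabels(occurrences$rel_start[i] - up, up + width + down)
    coords <- vapply(labs, function(r) .relToGenomic(p, st, r), numeric(1L))
    if (min(coords) < 1L || max(coords) > L) next  # truncated flank
    s <- .extractRegion(g, min(coords), max(coords), st)
    out <- c(out, stats::setNames(s, rownames(occurrences)[i]))
  }
  out
}

#' Scan sequences for a degenerate IUPAC pattern
#'
#' Exact sliding-window degenerate matching (D = A/G/T, R = A/G, W = A/T,
#' ...); every match offset is reported.
#'
#' @param sequences character vector of DNA sequences.
#' @param pattern IUPAC pattern string.
#' @return list with \code{matches} (data.frame seq_index, offset0) and
#'   \code{has_match} (logical per sequence).
#' @export
scanIupac <- function(sequences, pattern) {
  pletters <- strsplit(toupper(pattern), "")[[1L]]
  bad <- setdiff(pletters, names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "))
  w <- length(pletters)
  sets <- .IUPAC[pletters]
  res <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    chars <- strsplit(toupper(sequences[i]), "")[[1L]]
    L <- length(chars)
    if (L < w) { res[[i]] <- integer(0); next }
    noff <- L - w + 1L
    ok <- rep(TRUE, noff)
    for (k in seq_len(w)) {
      ok <- ok & chars[seq_len(noff) + k - 1L] %in% sets[[k]]
    }
    res[[i]] <- which(ok) - 1L
  }
  matches <- data.frame(
    seq_index = rep(seq_along(sequences), lengths(res)),
    offset0 = unlist(res, use.names = FALSE))
  list(matches = matches,
       has_match = lengths(res) > 0L)
}

#' Nucleotide composition around TSSs
#'
#' Per TSS-relative position (default -2..+3, skipping 0), the fraction of
#' each base, plus purine (A+G) and pyrimidine (C+T) aggregates at +1 and
#' -1. When a grouping vector is supplied the composition is computed per
#' group.
#'
#' @param tss width-1 TSS GRanges.
#' @param genome genome sequence.
#' @param from,to relative position range (0 skipped).
#' @param groups optional per-TSS grouping (e.g. leader class).
#' @return for each group, a list with \code{fractions} (4 x positions
#'   matrix), \code{purine_plus1}, \code{pyrimidine_minus1} (percent), and
#'   \code{n}.
#' @export
tssBaseComposition <- function(tss, genome, from = -2L, to = 3L,
                               groups = NULL) {
  g <- .genomeChar(genome)
  L <- nchar(g)
  labs <- setdiff(seq.int(from, to), 0L)
  pos <- GenomicRanges::start(tss)
  st <- as.character(GenomicRanges::strand(tss))
  basemat <- matrix(NA_character_, length(tss), length(labs),
                    dimnames = list(NULL, labs))
  for (j in seq_along(labs)) {
    coords <- ifelse(st == "+", .relToGenomic(pos, "+", labs[j]),
                     .relToGenomic(pos, "-", labs[j]))
    inb <- coords >= 1L & coords <= L
    b <- rep(NA_character_, length(tss))
    b[inb] <- substring(g, coords[inb], coords[inb])
    b[inb & st == "-"] <- unname(c(A = "T", C = "G", G = "C", T = "A",
                                   N = "N")[b[inb & st == "-"]])
    basemat[, j] <- b
  }
  if (is.null(groups)) groups <- rep("all", length(tss))
  out <- lapply(split(seq_along(tss), groups), function(idx) {
    frac <- apply(basemat[idx, , drop = FALSE], 2L, function(col) {
      col <- col[!is.na(col) & col != "N"]
      tab <- table(factor(col, levels = .BASES))
      as.numeric(tab) / max(sum(tab), 1L)
    })
    rownames(frac) <- .BASES
    p1 <- if ("1" %in% colnames(frac))
      100 * sum(frac[c("A", "G"), "1"]) else NA_real_
    m1 <- if ("-1" %in% colnames(frac))
      100 * sum(frac[c("C", "T"), "-1"]) else NA_real_
    list(fractions = frac, purine_plus1 = p1, pyrimidine_minus1 = m1,
         n = length(idx))
  })
  out
}

#' Scan ribosome-binding-site motifs around start codons
#'
#' Extracts a strand-oriented window around each record's start codon
#' (default -20..+10, +1 = first codon base) and scans it for the
#' degenerate Shine-Dalgarno pattern. The reported offset is the relative
#' label of the 5'-most match start.
#'
#' @param records UTR record data.frame (gene_id, leader_class).
#' @param annotation GRanges annotation.
#' @param genome genome sequence.
#' @param upstream,downstream window extents around the start codon.
#' @param pattern IUPAC pattern (default "GGDGRD").
#' @return list with \code{records} (input plus rbs_found, rbs_offset) and
#'   \code{summary} (fraction of records with a match per leader class).
#' @export
scanRbs <- function(records, annotation, genome,
                    upstream = 20L, downstream = 10L, pattern = "GGDGRD") {
  if (!nrow(records)) {
    return(list(records = cbind(records, rbs_found = logical(0),
                                rbs_offset = integer(0)),
                summary = numeric(0)))
  }
  g <- .genomeChar(genome)
  L <- nchar(g)
  idx <- match(records$gene_id, annotation$gene_id)
  st <- as.character(GenomicRanges::strand(annotation))[idx]
  cs <- ifelse(st == "+", GenomicRanges::start(annotation)[idx],
               GenomicRanges::end(annotation)[idx])
  lo <- ifelse(st == "+", cs - upstream, cs - downstream + 1L)
  hi <- ifelse(st == "+", cs + downstream - 1L, cs + upstream)
  usable <- lo >= 1L & hi <= L
  seqs <- rep(NA_character_, nrow(records))
  seqs[usable] <- substring(g, lo[usable], hi[usable])
  flip <- usable & st == "-"
  seqs[flip] <- .revcomp(seqs[flip])
  labs <- windowPositions(upstream, downstream)
  found <- rep(FALSE, nrow(records))
  offset <- rep(NA_integer_, nrow(records))
  scan <- scanIupac(seqs[usable], pattern)
  u <- which(usable)
  found[u] <- scan$has_match
  first <- scan$matches[!duplicated(scan$matches$seq_index), , drop = FALSE]
  offset[u[first$seq_index]] <- labs[first$offset0 + 1L]
  records$rbs_found <- found
  records$rbs_offset <- offset
  summary <- tapply(found, factor(records$leader_class,
                                  levels = c("umRNA", "lmRNA")),
                    function(x) 100 * mean(x), default = NA_real_)
  list(records = records, summary = summary)
}
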