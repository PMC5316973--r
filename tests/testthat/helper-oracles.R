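# Independent oracles: literal rule application for the TSS curation
# pipeline, exhaustive alignment enumeration, and set-membership motif
# matching. These deliberately avoid the package's implementation paths.

# --- weighted population SD, written straight from the definition -------
oracleWeightedSd <- function(x, w) {
  mu <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - mu)^2) / sum(w))
}

# --- TSS curation: transitive-closure clustering, recursive subdivision,
#     literal selection and merge rules --------------------------------
oracleCallStrand <- function(positions, counts, strand,
                             gap = 150, sd_thr = 15, min_reads = 3,
                             ratio = 0.5) {
  ord <- order(positions)
  positions <- positions[ord]; counts <- counts[ord]
  n <- length(positions)
  if (n == 0L) return(data.frame(position = integer(), count = integer()))

  # transitive closure over pairwise distance <= gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(positions[i] - positions[j]) <= gap &&
          comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  subdivide <- function(idx) {
    if (length(idx) <= 1L ||
        oracleWeightedSd(positions[idx], counts[idx]) < sd_thr)
      return(list(idx))
    gaps <- diff(positions[idx])
    cut <- which(gaps == max(gaps))[1L]
    c(subdivide(idx[seq_len(cut)]), subdivide(idx[-seq_len(cut)]))
  }

  out <- NULL
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    subs <- subdivide(idx)
    sel <- list()
    for (s in subs) {
      if (sum(counts[s]) < min_reads) next
      mx <- s[counts[s] == max(counts[s])]
      pick <- if (strand == "+") mx[which.min(positions[mx])]
              else mx[which.max(positions[mx])]
      sel[[length(sel) + 1L]] <- c(positions[pick], counts[pick])
    }
    if (!length(sel)) next
    tab <- do.call(rbind, sel)
    tab <- tab[order(tab[, 1L]), , drop = FALSE]
    # literal adjacent-pair merge
    repeat {
      if (nrow(tab) < 2L) break
      removed <- FALSE
      for (i in seq_len(nrow(tab) - 1L)) {
        sdv <- oracleWeightedSd(tab[i:(i + 1L), 1L], tab[i:(i + 1L), 2L])
        if (sdv < sd_thr) {
          if (tab[i, 2L] == tab[i + 1L, 2L]) {
            drop <- if (strand == "+") i + 1L else i
          } else drop <- i - 1L + which.min(tab[i:(i + 1L), 2L])
          tab <- tab[-drop, , drop = FALSE]
          removed <- TRUE
          break
        }
      }
      if (!removed) break
    }
    out <- rbind(out, tab)
  }
  if (is.null(out)) return(data.frame(position = integer(), count = integer()))
  out <- out[order(out[, 1L]), , drop = FALSE]
  data.frame(position = out[, 1L], count = out[, 2L])
}

# --- exhaustive global-alignment oracle -------------------------------
# Enumerates every order-preserving matching of positions between the two
# sequences (equivalent to every linear-gap alignment up to gap ordering);
# returns the optimal score and the set of identities attained by optimal
# alignments.
oracleAlign <- function(sa, sb, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(sa, "")[[1L]]; b <- strsplit(sb, "")[[1L]]
  n <- length(a); m <- length(b)
  best <- -Inf; idents <- numeric(0)
  for (k in 0:min(n, m)) {
    gapsc <- gap * (n + m - 2L * k)
    cols <- n + m - k
    if (k == 0L) {
      if (gapsc > best) { best <- gapsc; idents <- 0 }
      else if (gapsc == best) idents <- union(idents, 0)
      next
    }
    ca <- utils::combn(n, k); cb <- utils::combn(m, k)
    if (is.null(dim(ca))) ca <- matrix(ca, nrow = k)
    if (is.null(dim(cb))) cb <- matrix(cb, nrow = k)
    A <- matrix(a[ca], nrow = k); B <- matrix(b[cb], nrow = k)
    Mm <- matrix(0, ncol(ca), ncol(cb))
    for (base in c("A", "C", "G", "T"))
      Mm <- Mm + crossprod(A == base, B == base)
    sc <- match * Mm + mismatch * (k - Mm) + gapsc
    mx <- max(sc)
    if (mx > best) {
      best <- mx; idents <- unique(100 * Mm[sc == mx] / cols)
    } else if (mx == best) {
      idents <- union(idents, unique(100 * Mm[sc == mx] / cols))
    }
  }
  list(score = best, identities = idents)
}

# --- brute-force IUPAC matching by per-position set membership ---------
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

oracleIupacOffsets <- function(seq, pattern) {
  p <- strsplit(pattern, "")[[1L]]
  s <- strsplit(seq, "")[[1L]]
  w <- length(p); L <- length(s)
  if (L < w) return(integer(0))
  hits <- integer(0)
  for (off in 0:(L - w)) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!s[off + k] %in% ORACLE_IUPAC[[p[k]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# --- small fixture builders --------------------------------------------
# annotation GRanges from a plain data.frame
makeAnn <- function(df, seqname = "genome") {
  gr <- GenomicRanges::GRanges(seqname,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$feature_kind <-
    if ("feature_kind" %in% names(df)) df$feature_kind else "CDS"
  S4Vectors::mcols(gr)$cog_category <-
    if ("cog_category" %in% names(df)) df$cog_category else NA_character_
  gr
}

# width-1 TSS GRanges from a plain data.frame
makeTss <- function(df, seqname = "genome") {
  gr <- GenomicRanges::GRanges(seqname,
                               IRanges::IRanges(df$position, width = 1L),
                               strand = df$strand)
  S4Vectors::mcols(gr)$tss_id <-
    if ("tss_id" %in% names(df)) df$tss_id
    else sprintf("TSS%04d", seq_len(nrow(df)))
  S4Vectors::mcols(gr)$read_count <-
    if ("read_count" %in% names(df)) df$read_count else 10L
  S4Vectors::mcols(gr)$category <-
    if ("category" %in% names(df)) df$category else "P"
  S4Vectors::mcols(gr)$gene_id <-
    if ("gene_id" %in% names(df)) df$gene_id else NA_character_
  S4Vectors::mcols(gr)$distance_to_start <- NA_integer_
  gr
}

# sparse profile helper: positions/counts on one strand
makeProfile <- function(kind, L, fwd_pos = integer(0), fwd_count = integer(0),
                        rev_pos = integer(0), rev_count = integer(0)) {
  fwd <- integer(L); rev <- integer(L)
  fwd[fwd_pos] <- fwd_count
  rev[rev_pos] <- rev_count
  FivePrimeProfile(kind, fwd, rev)
}
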