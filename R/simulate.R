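# Synthetic genome / library simulator.
#
# Generates a toy single-replicon archaeal genome with planted regulatory
# truth: operons with a primary TSS upstream of (or at) the first start
# codon, BRE--TATA promoter elements with the TATA box in the -30..-20
# window, an "A" promoter-proximal element at -10, pyrimidine/purine
# preference at -1/+1, a leadered/leaderless UTR-length mixture with
# Shine-Dalgarno motifs in long-enough leaders, antisense/intergenic TSSs
# with full promoter support (ncRNA candidates, AT-shifted transcript
# bodies), and condition-dependent expression multipliers. Library
# profiles are then simulated on top of this truth: the TEX-treated
# library concentrates 5' ends at the TSS, the untreated library mixes
# intact 5' ends with processed ends 20-30 nt downstream plus a uniform
# degradation background, and strand-specific coverage profiles
# under-cover the first ~25 nt of each transcript.

# TATA box weight matrix over TTWTAW (rows A,C,G,T)
.TATA_PWM <- matrix(c(
  # T     T     W     T     A     W
  0.05, 0.05, 0.45, 0.05, 0.85, 0.45,   # A
  0.05, 0.05, 0.05, 0.05, 0.05, 0.05,   # C
  0.05, 0.05, 0.05, 0.05, 0.05, 0.05,   # G
  0.85, 0.85, 0.45, 0.85, 0.05, 0.45),  # T
  nrow = 4L, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))

.BASES <- c("A", "C", "G", "T")

#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every parameter of the planted-truth simulator. The defaults are
#' the study conditions assumed throughout the test-suite: a ~12\%
#' leaderless subpopulation, a 12-nt median leadered UTR, mean 5'-end read
#' depth of 20 per TSS, processed 5' ends offset 20--30 nt downstream in
#' the TEX-untreated library, and a 0.93 pyrimidine(-1)/purine(+1)
#' initiation-dinucleotide preference.
#'
#' @param genome_length genome size in bases (>= 1000).
#' @param gc_content background GC fraction in [0,1].
#' @param n_genes number of protein-coding genes.
#' @param n_operons number of operons (<= n_genes); genes are partitioned
#'   into operons and only the operon-first gene receives a primary TSS.
#' @param leaderless_fraction fraction of operon-first genes whose mRNA is
#'   leaderless (UTR <= 5 nt; 70\% of these have UTR exactly 0).
#' @param utr_length_median target median UTR length (nt) of leadered genes.
#' @param tss_read_depth_mean Poisson mean of 5'-end reads per planted TSS.
#' @param tex_minus_processed_offset_range integer length-2 vector; processed
#'   5' ends in the TEX- library fall uniformly this many nt downstream.
#' @param degradation_rate background 5' ends per base per strand in the
#'   TEX- library (the TEX+ library gets a tenth of this).
#' @param n_conditions number of expression conditions.
#' @param condition_names labels; first is the reference condition.
#' @param fold_change_spec list(fraction=, fold=): per non-reference
#'   condition, each transcript is differentially expressed with this
#'   probability, at multiplier fold or 1/fold.
#' @param seed integer seed; fully determines every output.
#' @param gene_length_range integer length-2 vector of CDS lengths.
#' @param n_antisense,n_intergenic planted antisense / intergenic TSSs
#'   (ncRNA candidates with full promoter support).
#' @param n_structural flagged rRNA/tRNA annotation entries (no TSS).
#' @param purine_plus_one_rate planted purine rate at +1 (leadered TSSs).
#' @param pyrimidine_minus_one_rate planted pyrimidine rate at -1.
#' @param start_codon_freqs named probabilities over start codons.
#' @param inr_rate probability of planting the weak initiator GAGAT at
#'   +2..+6 when the UTR allows it.
#' @param expression_base_depth per-base coverage at multiplier 1.
#' @param expression_background_rate off-transcript coverage rate per base.
#' @param ncrna_gc GC fraction planted over ncRNA transcript bodies.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(genome_length = 60000L,
                             gc_content = 0.51,
                             n_genes = 40L,
                             n_operons = 30L,
                             leaderless_fraction = 0.12,
                             utr_length_median = 12L,
                             tss_read_depth_mean = 20,
                             tex_minus_processed_offset_range = c(20L, 30L),
                             degradation_rate = 0.01,
                             n_conditions = 3L,
                             condition_names = c("YPS", "MMC", "MMF"),
                             fold_change_spec = list(fraction = 0.25, fold = 2),
                             seed = 1L,
                             gene_length_range = c(200L, 600L),
                             n_antisense = 3L,
                             n_intergenic = 5L,
                             n_structural = 2L,
                             purine_plus_one_rate = 0.93,
                             pyrimidine_minus_one_rate = 0.93,
                             start_codon_freqs = c(ATG = 0.90, GTG = 0.07, TTG = 0.03),
                             inr_rate = 0.3,
                             expression_base_depth = 50,
                             expression_background_rate = 0.02,
                             ncrna_gc = 0.48) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_content = gc_content, n_genes = as.integer(n_genes),
              n_operons = as.integer(n_operons),
              leaderless_fraction = leaderless_fraction,
              utr_length_median = as.integer(utr_length_median),
              tss_read_depth_mean = tss_read_depth_mean,
              tex_minus_processed_offset_range =
                as.integer(tex_minus_processed_offset_range),
              degradation_rate = degradation_rate,
              n_conditions = as.integer(n_conditions),
              condition_names = condition_names,
              fold_change_spec = fold_change_spec,
              seed = as.integer(seed),
              gene_length_range = as.integer(gene_length_range),
              n_antisense = as.integer(n_antisense),
              n_intergenic = as.integer(n_intergenic),
              n_structural = as.integer(n_structural),
              purine_plus_one_rate = purine_plus_one_rate,
              pyrimidine_minus_one_rate = pyrimidine_minus_one_rate,
              start_codon_freqs = start_codon_freqs,
              inr_rate = inr_rate,
              expression_base_depth = expression_base_depth,
              expression_background_rate = expression_background_rate,
              ncrna_gc = ncrna_gc)
  if (cfg$genome_length < 1000L) stop("genome_length must be >= 1000")
  if (cfg$gc_content < 0 || cfg$gc_content > 1)
    stop("gc_content must lie in [0, 1]")
  if (cfg$leaderless_fraction < 0 || cfg$leaderless_fraction > 1)
    stop("leaderless_fraction must lie in [0, 1]")
  if (cfg$n_operons > cfg$n_genes) stop("n_operons must be <= n_genes")
  if (cfg$n_conditions != length(cfg$condition_names))
    stop("condition_names must have n_conditions entries")
  if (length(cfg$tex_minus_processed_offset_range) != 2L ||
      diff(cfg$tex_minus_processed_offset_range) < 0L)
    stop("tex_minus_processed_offset_range must be an increasing interval")
  class(cfg) <- "SimulationConfig"
  cfg
}

# sample n bases at a given GC fraction
.sampleBases <- function(n, gc) {
  sample(.BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.samplePwm <- function(pwm) {
  paste0(apply(pwm, 2L, function(p) sample(.BASES, 1L, prob = p)),
         collapse = "")
}

# write a strand-oriented motif into the genome character vector at
# relative labels relStart..(relStart+w-1) (0 skipped) around `pos`
.plantRel <- function(g, pos, strand, relStart, motif) {
  w <- nchar(motif)
  labs <- .relLabels(relStart, w)
  coords <- vapply(labs, function(r) .relToGenomic(pos, strand, r), numeric(1L))
  bases <- strsplit(motif, "")[[1L]]
  if (strand == "-") {
    # the motif reads 5'->3' along decreasing coordinates: write the
    # complement of base i at the coordinate of label i
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    bases <- unname(comp[bases])
  }
  ok <- coords >= 1L & coords <= length(g)
  g[coords[ok]] <- bases[ok]
  g
}

#' Generate a synthetic genome with planted regulatory truth
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a list with elements \code{genome} (DNAStringSet, one record),
#'   \code{annotation} (GRanges of CDS/rRNA/tRNA features with
#'   \code{gene_id}, \code{feature_kind}, \code{cog_category}),
#'   \code{truth} (list of planted-truth tables: \code{tss},
#'   \code{genes}, \code{operons}, \code{promoters}, \code{sd},
#'   \code{ncrna}, \code{multipliers}) and \code{config}.
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  L <- config$genome_length
  nG <- config$n_genes
  nOp <- config$n_operons

  # operon sizes and strands
  sizes <- rep(1L, nOp)
  extra <- nG - nOp
  if (extra > 0L) {
    add <- table(factor(sample.int(nOp, extra, replace = TRUE), levels = seq_len(nOp)))
    sizes <- sizes + as.integer(add)
  }
  op_strand <- sample(c("+", "-"), nOp, replace = TRUE)
  gene_len <- sample(seq(config$gene_length_range[1L],
                         config$gene_length_range[2L]), nG, replace = TRUE)

  margin_up <- 360L; intra_gap <- 20L; tail_gap <- 40L
  len_by_op <- split(gene_len, rep(seq_len(nOp), sizes))
  op_width <- vapply(seq_len(nOp), function(i) {
    margin_up + sum(len_by_op[[i]]) + intra_gap * (sizes[i] - 1L) + tail_gap
  }, integer(1L))
  struct_width <- rep(160L, config$n_structural)
  widths <- c(op_width, struct_width)
  nBlk <- length(widths)
  spacer <- 200L
  need <- sum(widths) + spacer * (nBlk + 1L)
  if (need > L)
    stop(sprintf("genome too short for requested gene count: need >= %d bases, have %d",
                 need, L))
  pad <- (L - need) %/% (nBlk + 1L)
  spacers <- rep(spacer + pad, nBlk + 1L)
  spacers[nBlk + 1L] <- spacers[nBlk + 1L] + (L - need) %% (nBlk + 1L)

  blk_order <- sample.int(nBlk)
  blk_left <- integer(nBlk); blk_right <- integer(nBlk)
  cursor <- 0L
  for (k in seq_len(nBlk)) {
    cursor <- cursor + spacers[k]
    b <- blk_order[k]
    blk_left[b] <- cursor + 1L
    blk_right[b] <- cursor + widths[b]
    cursor <- blk_right[b]
  }
  spacer_bounds <- cbind(
    c(1L, sort(blk_right) + 1L),
    c(sort(blk_left) - 1L, L))

  g <- .sampleBases(L, config$gc_content)

  # gene coordinates
  genes <- vector("list", nOp)
  gid <- 0L
  for (i in seq_len(nOp)) {
    lens <- len_by_op[[i]]
    st <- op_strand[i]
    n <- sizes[i]
    starts <- integer(n); ends <- integer(n)
    if (st == "+") {
      s <- blk_left[i] + margin_up
      for (j in seq_len(n)) {
        starts[j] <- s; ends[j] <- s + lens[j] - 1L
        s <- ends[j] + intra_gap + 1L
      }
    } else {
      e <- blk_right[i] - margin_up
      for (j in seq_len(n)) {
        ends[j] <- e; starts[j] <- e - lens[j] + 1L
        e <- starts[j] - intra_gap - 1L
      }
    }
    gid_new <- gid + seq_len(n)
    genes[[i]] <- data.frame(
      gene_id = sprintf("SYN_%04d", gid_new),
      start = starts, end = ends, strand = st,
      operon_id = sprintf("OP%04d", i), pos_in_operon = seq_len(n),
      length = lens, stringsAsFactors = FALSE)
    gid <- gid + n
  }
  genes <- do.call(rbind, genes)
  genes$feature_kind <- "CDS"

  # flagged structural RNA genes (no planted TSS)
  if (config$n_structural > 0L) {
    sidx <- nOp + seq_len(config$n_structural)
    kinds <- rep(c("rRNA", "tRNA"), length.out = config$n_structural)
    struct <- data.frame(
      gene_id = sprintf("SYNR_%02d", seq_len(config$n_structural)),
      start = blk_left[sidx] + 20L, end = blk_left[sidx] + 139L,
      strand = sample(c("+", "-"), config$n_structural, replace = TRUE),
      operon_id = NA_character_, pos_in_operon = NA_integer_,
      length = 120L, feature_kind = kinds, stringsAsFactors = FALSE)
  } else struct <- NULL

  # UTR lengths and TSSs for operon-first genes
  first <- genes[genes$pos_in_operon == 1L, ]
  nF <- nrow(first)
  leaderless <- stats::runif(nF) < config$leaderless_fraction
  utr <- integer(nF)
  lmu <- leaderless
  utr[lmu] <- ifelse(stats::runif(sum(lmu)) < 0.7, 0L,
                     sample(1:5, sum(lmu), replace = TRUE))
  med <- max(config$utr_length_median, 7L)
  p_geom <- 1 - 0.5^(1 / (med - 6L + 1L))
  utr[!lmu] <- pmin(6L + stats::rgeom(sum(!lmu), p_geom), 250L)
  tss_pos <- ifelse(first$strand == "+", first$start - utr, first$end + utr)

  genes$utr_length <- NA_integer_
  genes$leader_class <- NA_character_
  genes$utr_length[match(first$gene_id, genes$gene_id)] <- utr
  genes$leader_class[match(first$gene_id, genes$gene_id)] <-
    ifelse(leaderless, "lmRNA", "umRNA")

  # start codons for every CDS
  codons <- sample(names(config$start_codon_freqs), nG, replace = TRUE,
                   prob = config$start_codon_freqs)
  genes$start_codon <- codons
  for (j in seq_len(nG)) {
    cp <- if (genes$strand[j] == "+") genes$start[j] else genes$end[j]
    g <- .plantRel(g, cp, genes$strand[j], 1L, codons[j])
  }

  # COG categories (coarse, R/S-heavy like an archaeal proteome)
  cog_pool <- c("R", "S", "E", "C", "P", "F", "H", "J", "K", "L", "M", "O", "T")
  cog_w <- c(5, 4, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1)
  has_cog <- stats::runif(nG) >= 0.35
  genes$cog_category <- NA_character_
  genes$cog_category[has_cog] <- sample(cog_pool, sum(has_cog),
                                        replace = TRUE, prob = cog_w)

  # antisense / intergenic TSSs (ncRNA candidates)
  nc <- list()
  long_enough <- which(genes$feature_kind == "CDS" & genes$length >= 300L)
  nA <- min(config$n_antisense, length(long_enough))
  if (nA > 0L) {
    tgt <- sample(long_enough, nA)
    for (k in seq_len(nA)) {
      e <- sample(80:150, 1L)
      gs <- genes$start[tgt[k]]; ge <- genes$end[tgt[k]]
      ncs <- if (genes$strand[tgt[k]] == "+") "-" else "+"
      p <- if (ncs == "-") sample(seq(gs + e, ge - 40L), 1L)
           else sample(seq(gs + 40L, ge - e), 1L)
      nc[[length(nc) + 1L]] <- data.frame(
        position = p, strand = ncs, class = "antisense", extent = e,
        target_gene = genes$gene_id[tgt[k]], stringsAsFactors = FALSE)
    }
  }
  wide_sp <- which(spacer_bounds[, 2L] - spacer_bounds[, 1L] >= 220L)
  nI <- min(config$n_intergenic, length(wide_sp))
  if (nI > 0L) {
    sp <- sample(wide_sp, nI)
    for (k in seq_len(nI)) {
      e <- sample(60:120, 1L)
      sL <- spacer_bounds[sp[k], 1L]; sR <- spacer_bounds[sp[k], 2L]
      ncs <- sample(c("+", "-"), 1L)
      p <- if (ncs == "+") sample(seq(sL + 45L, sR - e), 1L)
           else sample(seq(sL + e, sR - 45L), 1L)
      nc[[length(nc) + 1L]] <- data.frame(
        position = p, strand = ncs, class = "intergenic", extent = e,
        target_gene = NA_character_, stringsAsFactors = FALSE)
    }
  }
  nc <- if (length(nc)) do.call(rbind, nc) else
    data.frame(position = integer(), strand = character(),
               class = character(), extent = integer(),
               target_gene = character(), stringsAsFactors = FALSE)

  # AT-shift ncRNA transcript bodies before promoter planting
  if (nrow(nc)) {
    for (k in seq_len(nrow(nc))) {
      p <- nc$position[k]; e <- nc$extent[k]
      rng <- if (nc$strand[k] == "+") p:(p + e - 1L) else (p - e + 1L):p
      g[rng] <- .sampleBases(length(rng), config$ncrna_gc)
    }
  }

  # assemble the full TSS truth table
  tss <- data.frame(position = tss_pos, strand = first$strand,
                    category = "P", gene_id = first$gene_id,
                    utr_length = utr, stringsAsFactors = FALSE)
  if (nrow(nc))
    tss <- rbind(tss, data.frame(
      position = nc$position, strand = nc$strand,
      category = ifelse(nc$class == "antisense", "A", "N"),
      gene_id = NA_character_, utr_length = NA_integer_,
      stringsAsFactors = FALSE))
  ord <- order(tss$position)
  tss <- tss[ord, , drop = FALSE]
  tss$tss_id <- sprintf("TSS%04d", seq_len(nrow(tss)))
  rownames(tss) <- NULL
  if (nrow(nc)) {
    nc$tss_id <- tss$tss_id[match(paste(nc$position, nc$strand),
                                  paste(tss$position, tss$strand))]
  }

  # promoter elements for every TSS (primary and ncRNA alike)
  prom <- data.frame(tss_id = tss$tss_id, tata_rel_start = NA_integer_,
                     tata_center_rel = NA_real_, tata_seq = NA_character_,
                     bre_rel_start = NA_integer_, has_inr = FALSE,
                     stringsAsFactors = FALSE)
  for (k in seq_len(nrow(tss))) {
    p <- tss$position[k]; st <- tss$strand[k]
    s <- sample(-30:-25, 1L)
    tata <- .samplePwm(.TATA_PWM)
    g <- .plantRel(g, p, st, s, tata)
    bre <- paste0(sample(.BASES, 6L, replace = TRUE,
                         prob = c(0.7, 0.1, 0.1, 0.1)), collapse = "")
    g <- .plantRel(g, p, st, s - 6L, bre)
    g <- .plantRel(g, p, st, -10L, "A")
    prom$tata_rel_start[k] <- s
    prom$tata_center_rel[k] <- s + 2.5
    prom$tata_seq[k] <- tata
    prom$bre_rel_start[k] <- s - 6L
    # initiation dinucleotide
    m1 <- if (stats::runif(1) < config$pyrimidine_minus_one_rate)
      sample(c("T", "C"), 1L) else sample(c("A", "G"), 1L)
    g <- .plantRel(g, p, st, -1L, m1)
    u <- tss$utr_length[k]
    if (is.na(u) || u > 0L) {
      p1 <- if (stats::runif(1) < config$purine_plus_one_rate)
        sample(c("A", "G"), 1L) else sample(c("T", "C"), 1L)
      g <- .plantRel(g, p, st, 1L, p1)
    }
    # the weak initiator is only planted where it cannot collide with the
    # Shine-Dalgarno element planted at -9..-4 relative to the start codon
    if (!is.na(u) && u >= 16L && stats::runif(1) < config$inr_rate) {
      g <- .plantRel(g, p, st, 2L, "GAGAT")
      prom$has_inr[k] <- TRUE
    }
  }

  # Shine-Dalgarno for leadered first genes with room in the UTR; planted
  # after the promoter loop so the initiation dinucleotide cannot clip it
  sd_ok <- !lmu & utr >= 9L
  sd_tab <- data.frame(gene_id = first$gene_id[sd_ok],
                       rel_start = rep(-9L, sum(sd_ok)),
                       motif = rep(NA_character_, sum(sd_ok)),
                       stringsAsFactors = FALSE)
  for (j in which(sd_ok)) {
    m <- .sampleIupac("GGDGRD")
    sd_tab$motif[match(first$gene_id[j], sd_tab$gene_id)] <- m
    cp <- if (first$strand[j] == "+") first$start[j] else first$end[j]
    g <- .plantRel(g, cp, first$strand[j], -9L, m)
  }

  # re-assert start codons: a TSS at/near the ATG may have overwritten it
  for (j in seq_len(nG)) {
    cp <- if (genes$strand[j] == "+") genes$start[j] else genes$end[j]
    g <- .plantRel(g, cp, genes$strand[j], 1L, codons[j])
  }

  # expression multipliers per transcript per condition
  all_tx <- c(genes$gene_id, if (!is.null(struct)) struct$gene_id,
              nc$tss_id)
  mult <- matrix(1, nrow = length(all_tx), ncol = config$n_conditions,
                 dimnames = list(all_tx, config$condition_names))
  if (config$n_conditions > 1L) {
    for (ci in 2:config$n_conditions) {
      de <- stats::runif(length(all_tx)) < config$fold_change_spec$fraction
      updn <- sample(c(config$fold_change_spec$fold,
                       1 / config$fold_change_spec$fold),
                     length(all_tx), replace = TRUE)
      mult[de, ci] <- updn[de]
    }
  }
  if (!is.null(struct)) mult[struct$gene_id, ] <- 50

  all_genes <- rbind(genes,
                     if (!is.null(struct)) {
                       struct$utr_length <- NA_integer_
                       struct$leader_class <- NA_character_
                       struct$start_codon <- NA_character_
                       struct$cog_category <- NA_character_
                       struct[, colnames(genes)]
                     })
  ann <- GenomicRanges::GRanges(
    seqnames = "synthetic",
    ranges = IRanges::IRanges(all_genes$start, all_genes$end),
    strand = all_genes$strand)
  S4Vectors::mcols(ann)$gene_id <- all_genes$gene_id
  S4Vectors::mcols(ann)$feature_kind <- all_genes$feature_kind
  S4Vectors::mcols(ann)$cog_category <- all_genes$cog_category
  S4Vectors::mcols(ann)$product <- ifelse(all_genes$feature_kind == "CDS",
                                          "synthetic protein", "structural RNA")

  genome <- Biostrings::DNAStringSet(paste0(g, collapse = ""))
  names(genome) <- sprintf("SYN_seed%d", config$seed)

  operons <- genes[!is.na(genes$operon_id),
                   c("operon_id", "gene_id", "pos_in_operon", "strand")]

  list(genome = genome, annotation = ann,
       truth = list(tss = tss, genes = all_genes, operons = operons,
                    promoters = prom, sd = sd_tab, ncrna = nc,
                    multipliers = mult),
       config = config)
}

#' Simulate a dRNA-seq 5'-end profile from planted truth
#'
#' TEX+ places 90\% of each TSS's reads at the exact position and 10\% at
#' +/-1 nt; TEX- splits reads 50/35/15 between the TSS, processed positions
#' 20--30 nt downstream, and uniform background, and additionally carries a
#' per-base degradation background (the TEX+ background rate is a tenth of
#' the TEX- rate).
#'
#' @param truth the \code{truth} element of \code{\link{simulateGenome}}.
#' @param libraryKind \code{"TEX_PLUS"} or \code{"TEX_MINUS"}.
#' @param config the matching \code{\link{simulationConfig}}.
#' @return a \linkS4class{FivePrimeProfile}.
#' @export
simulateFivePrimeProfile <- function(truth,
                                     libraryKind = c("TEX_PLUS", "TEX_MINUS"),
                                     config) {
  libraryKind <- match.arg(libraryKind)
  set.seed(config$seed + if (libraryKind == "TEX_PLUS") 101L else 102L)
  L <- config$genome_length
  depth <- config$tss_read_depth_mean
  offr <- config$tex_minus_processed_offset_range
  pos_f <- integer(0); pos_r <- integer(0)
  tss <- truth$tss
  for (k in seq_len(nrow(tss))) {
    p <- tss$position[k]; st <- tss$strand[k]
    n <- stats::rpois(1L, depth)
    if (n == 0L) next
    if (libraryKind == "TEX_PLUS") {
      n0 <- stats::rbinom(1L, n, 0.9)
      nm <- stats::rbinom(1L, n - n0, 0.5)
      np <- n - n0 - nm
      pts <- c(rep(p, n0), rep(p - 1L, nm), rep(p + 1L, np))
    } else {
      parts <- stats::rmultinom(1L, n, c(0.5, 0.35, 0.15))[, 1L]
      offs <- sample(offr[1L]:offr[2L], parts[2L], replace = TRUE)
      proc <- if (st == "+") p + offs else p - offs
      bg <- sample.int(L, parts[3L], replace = TRUE)
      pts <- c(rep(p, parts[1L]), proc, bg)
    }
    pts <- pts[pts >= 1L & pts <= L]
    if (st == "+") pos_f <- c(pos_f, pts) else pos_r <- c(pos_r, pts)
  }
  bg_rate <- config$degradation_rate *
    if (libraryKind == "TEX_PLUS") 0.1 else 1
  fwd <- tabulate(pos_f, L) + stats::rpois(L, bg_rate)
  rev <- tabulate(pos_r, L) + stats::rpois(L, bg_rate)
  FivePrimeProfile(libraryKind, fwd, rev)
}

#' Simulate a strand-specific coverage profile for one condition
#'
#' Per-base coverage over each transcript body is Poisson with mean
#' multiplier x base depth; the first ~25 nt downstream of the 5' end are
#' under-covered (x0.2), emulating loss of proximal 5' termini in
#' strand-specific libraries.
#'
#' @param truth the \code{truth} element of \code{\link{simulateGenome}}.
#' @param condition one of the configured condition names.
#' @param config the matching \code{\link{simulationConfig}}.
#' @return a \linkS4class{CoverageProfile}.
#' @export
simulateExpressionProfile <- function(truth, condition, config) {
  ci <- match(condition, config$condition_names)
  if (is.na(ci)) stop("unknown condition label: ", condition)
  set.seed(config$seed + 200L + ci)
  L <- config$genome_length
  fwd <- numeric(L); rev <- numeric(L)
  base <- config$expression_base_depth
  drop5 <- 25L
  addTx <- function(fwd, rev, start, end, strand, lam) {
    len <- end - start + 1L
    lamv <- rep(lam, len)
    k <- min(drop5, len)
    if (strand == "+") lamv[seq_len(k)] <- lam * 0.2
    else lamv[len - seq_len(k) + 1L] <- lam * 0.2
    depth <- stats::rpois(len, lamv)
    if (strand == "+") fwd[start:end] <- fwd[start:end] + depth
    else rev[start:end] <- rev[start:end] + depth
    list(fwd, rev)
  }
  genes <- truth$genes
  for (j in seq_len(nrow(genes))) {
    lam <- truth$multipliers[genes$gene_id[j], ci] * base
    res <- addTx(fwd, rev, genes$start[j], genes$end[j], genes$strand[j], lam)
    fwd <- res[[1L]]; rev <- res[[2L]]
  }
  nc <- truth$ncrna
  if (nrow(nc)) {
    for (k in seq_len(nrow(nc))) {
      p <- nc$position[k]; e <- nc$extent[k]
      lam <- truth$multipliers[nc$tss_id[k], ci] * base
      rng <- if (nc$strand[k] == "+") c(p, p + e - 1L) else c(p - e + 1L, p)
      res <- addTx(fwd, rev, rng[1L], rng[2L], nc$strand[k], lam)
      fwd <- res[[1L]]; rev <- res[[2L]]
    }
  }
  if (config$expression_background_rate > 0) {
    fwd <- fwd + stats::rpois(L, config$expression_background_rate)
    rev <- rev + stats::rpois(L, config$expression_background_rate)
  }
  CoverageProfile(fwd, rev)
}

#' Simulate a pair of diverged genomes sharing annotation and TSSs
#'
#' Starting from one simulated genome, a second genome is derived by
#' substituting bases at region-specific rates (ORF bodies, promoter
#' -40..-21, 5' UTR, upstream -100..-41, background). Both genomes share
#' coordinates, annotation and TSS positions, mimicking a pair of closely
#' related genomes whose orthologs and upstream regions can be compared.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param rates named substitution rates for \code{orf}, \code{promoter},
#'   \code{utr}, \code{upstream}, \code{background}.
#' @return list with \code{genome_a}, \code{genome_b} (DNAStringSet),
#'   \code{annotation}, \code{truth}, \code{rates}.
#' @export
simulateGenomePair <- function(config,
                               rates = c(orf = 0.25, promoter = 0.37,
                                         utr = 0.42, upstream = 0.5,
                                         background = 0.5)) {
  sim <- simulateGenome(config)
  L <- config$genome_length
  cls <- rep("background", L)
  genes <- sim$truth$genes
  cds <- genes[genes$feature_kind == "CDS", ]
  for (j in seq_len(nrow(cds))) cls[cds$start[j]:cds$end[j]] <- "orf"
  tss <- sim$truth$tss[sim$truth$tss$category == "P", ]
  for (k in seq_len(nrow(tss))) {
    p <- tss$position[k]; st <- tss$strand[k]; u <- tss$utr_length[k]
    reg <- function(a, b) { # relative labels a..b (both negative)
      r <- sort(c(.relToGenomic(p, st, a), .relToGenomic(p, st, b)))
      seq(max(1L, r[1L]), min(L, r[2L]))
    }
    cls[reg(-100L, -41L)] <- "upstream"
    cls[reg(-40L, -21L)] <- "promoter"
    if (u > 0L) {
      r <- if (st == "+") p:(p + u - 1L) else (p - u + 1L):p
      cls[r] <- "utr"
    }
  }
  set.seed(config$seed + 300L)
  ga <- strsplit(as.character(sim$genome[[1L]]), "")[[1L]]
  mut <- stats::runif(L) < rates[cls]
  gb <- ga
  idx <- which(mut)
  if (length(idx)) {
    shift <- sample.int(3L, length(idx), replace = TRUE)
    cur <- match(ga[idx], .BASES)
    gb[idx] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  genome_b <- Biostrings::DNAStringSet(paste0(gb, collapse = ""))
  names(genome_b) <- sprintf("SYNB_seed%d", config$seed)
  list(genome_a = sim$genome, genome_b = genome_b,
       annotation = sim$annotation, truth = sim$truth, rates = rates)
}
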