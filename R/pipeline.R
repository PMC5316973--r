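# End-to-end orchestration over a simulated or loaded data set.

#' Run the full primary-transcriptome pipeline
#'
#' Simulates a genome and libraries from a \code{\link{simulationConfig}}
#' (or consumes pre-built inputs), then runs TSS calling, UTR analysis,
#' promoter motif discovery, TSS-proximal composition, RBS scanning,
#' expression quantification with a fold-change screen, and ncRNA calling.
#' Every stage is a pure function of the inputs and the configuration, so
#' a fixed seed reproduces the manifest exactly.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param calling \code{\link{callingParams}}.
#' @param motif_width width for promoter motif discovery (default 6, the
#'   TATA-box scale).
#' @param outdir optional directory; when given, the TSS table/BED, UTR
#'   table, expression table and ncRNA table are written there.
#' @return a manifest list: inputs (config echo), per-stage record counts
#'   (TSS counts per category, UTR/leader counts, motif consensus,
#'   fold-change screen size, ncRNA counts), and the stage outputs
#'   themselves under \code{$results}.
#' @export
runPipeline <- function(config = simulationConfig(),
                        calling = callingParams(),
                        motif_width = 6L, outdir = NULL) {
  sim <- simulateGenome(config)
  texp <- simulateFivePrimeProfile(sim$truth, "TEX_PLUS", config)
  texm <- simulateFivePrimeProfile(sim$truth, "TEX_MINUS", config)
  profiles <- stats::setNames(lapply(config$condition_names, function(cn)
    simulateExpressionProfile(sim$truth, cn, config)),
    config$condition_names)

  tss <- callTss(texp, texm, sim$annotation, calling)
  cat_counts <- table(factor(tss$category, levels = c("P", "S", "I", "A", "N")))

  utr <- utrTable(tss, sim$annotation, sim$genome)
  utr_stats <- if (nrow(utr)) utrLengthDistribution(utr$utr_length) else NULL

  p_tss <- tss[tss$category == "P"]
  win <- promoterWindows(p_tss, sim$genome, upstream = 50L, downstream = 10L)
  win_ok <- win[!win$truncated, ]
  motif <- if (nrow(win_ok) >= 10L)
    discoverMotif(win_ok$sequence, motif_width, seed = config$seed)
  else NULL

  comp <- tssBaseComposition(p_tss, sim$genome)

  rbs <- if (nrow(utr)) scanRbs(utr, sim$annotation, sim$genome) else NULL

  expr <- expressionTable(profiles, sim$annotation)
  screens <- list()
  ref <- config$condition_names[1L]
  for (cn in setdiff(config$condition_names, ref)) {
    screens[[paste0(cn, "_vs_", ref)]] <-
      foldChange(expr, cn, ref, min_fold = 2)
  }

  # TATA occurrences mapped back to TSS-relative labels for ncRNA support
  tata_occ <- NULL
  if (!is.null(motif) && nrow(motif$occurrences)) {
    occ <- motif$occurrences
    tata_occ <- data.frame(
      tss_id = win_ok$tss_id[occ$seq_index],
      rel_start = offsetToRelative(occ$offset0, 50L, 10L),
      width = motif_width, stringsAsFactors = FALSE)
  }
  # ncRNA calling needs occurrences for A/N TSSs too: scan their windows
  an_tss <- tss[tss$category %in% c("A", "N")]
  if (length(an_tss)) {
    win_an <- promoterWindows(an_tss, sim$genome, 50L, 10L)
    win_an <- win_an[!win_an$truncated, ]
    if (nrow(win_an) && !is.null(motif)) {
      sc <- .scanPwm(win_an$sequence, frequencyMatrix(motif$model),
                     motif$model@background)
      hit <- sc$score >= 0  # positive log-odds = better than background
      tata_occ <- rbind(tata_occ, data.frame(
        tss_id = win_an$tss_id[hit],
        rel_start = offsetToRelative(sc$offset0[hit], 50L, 10L),
        width = motif_width, stringsAsFactors = FALSE))
    }
  }
  ncrna <- if (!is.null(tata_occ))
    callNcRnas(tss, tata_occ, profiles[[ref]], sim$genome,
               tata_width = motif_width)
  else NULL
  if (!is.null(ncrna) && nrow(ncrna))
    ncrna <- ncRnaExpressionResponse(ncrna, profiles)

  results <- list(simulation = sim, tss = tss, utr = utr, motif = motif,
                  composition = comp, rbs = rbs, expression = expr,
                  screens = screens, ncrna = ncrna)

  manifest <- list(
    seed = config$seed,
    genome_length = config$genome_length,
    n_genes = config$n_genes,
    tss_counts = as.list(cat_counts),
    n_tss = length(tss),
    n_utr_records = nrow(utr),
    utr_median = if (!is.null(utr_stats)) utr_stats$median else NA,
    leaderless_pct = if (nrow(utr))
      100 * mean(utr$leader_class == "lmRNA") else NA,
    motif_consensus = if (!is.null(motif)) motifConsensus(motif$model)
                      else NA,
    n_fold_change_pass = vapply(screens, function(s) sum(s$pass),
                                integer(1L)),
    n_ncrna = if (!is.null(ncrna)) nrow(ncrna) else 0L,
    results = results)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeTssTable(tss, file.path(outdir, "tss.tsv"))
    writeTssBed(tss, file.path(outdir, "tss.bed"))
    utils::write.table(utr, file.path(outdir, "utr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expr, file.path(outdir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ncrna))
      utils::write.table(ncrna, file.path(outdir, "ncrna.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  manifest
}

# best PWM hit per sequence (log-odds vs 0-order background)
.scanPwm <- function(sequences, freq, background) {
  w <- ncol(freq)
  logodds <- log(freq) - log(background)
  n <- length(sequences)
  best_off <- integer(n); best_sc <- numeric(n)
  for (i in seq_len(n)) {
    ch <- match(strsplit(sequences[i], "")[[1L]], .BASES)
    L <- length(ch)
    noff <- L - w + 1L
    sc <- vapply(seq_len(noff), function(j)
      sum(logodds[cbind(ch[j:(j + w - 1L)], seq_len(w))]), numeric(1L))
    best_off[i] <- which.max(sc) - 1L
    best_sc[i] <- max(sc)
  }
  list(offset0 = best_off, score = best_sc)
}
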