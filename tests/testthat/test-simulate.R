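# Planted-truth generator: determinism, promoter placement, class balance,
# and library signal structure.

test_that("identical configuration yields byte-identical outputs", {
  cfg <- simulationConfig(seed = 7)
  s1 <- simulateGenome(cfg)
  s2 <- simulateGenome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$tss, s2$truth$tss)
  expect_identical(s1$truth$multipliers, s2$truth$multipliers)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeGenomeFasta(s1$genome, f1)
  writeGenomeFasta(s2$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  p1 <- simulateFivePrimeProfile(s1$truth, "TEX_PLUS", cfg)
  p2 <- simulateFivePrimeProfile(s2$truth, "TEX_PLUS", cfg)
  expect_identical(p1@fwd, p2@fwd)
})

test_that("a too-small genome for the gene count is refused", {
  expect_error(simulateGenome(simulationConfig(genome_length = 2000L,
                                               n_genes = 30L,
                                               n_operons = 30L)),
               "genome too short")
})

test_that("leaderless_fraction = 0 forces every planted UTR above 5 nt", {
  cfg <- simulationConfig(leaderless_fraction = 0, seed = 3)
  sim <- simulateGenome(cfg)
  u <- sim$truth$tss$utr_length[sim$truth$tss$category == "P"]
  expect_true(all(u > 5L))
})

test_that("planted promoter elements sit where the truth says", {
  cfg <- simulationConfig(seed = 11)
  sim <- simulateGenome(cfg)
  g <- as.character(sim$genome[[1L]])
  tss <- sim$truth$tss
  prom <- sim$truth$promoters
  # every TATA center in -30..-20 and an A at -10, for every planted TSS
  expect_true(all(prom$tata_center_rel >= -30 & prom$tata_center_rel <= -20))
  for (k in seq_len(nrow(tss))) {
    p <- tss$position[k]; st <- tss$strand[k]
    win <- promoterWindows(makeTss(data.frame(position = p, strand = st)),
                           g, upstream = 50L, downstream = 10L)
    labs <- c(-50:-1, 1:10)
    chars <- strsplit(win$sequence, "")[[1L]]
    expect_identical(chars[which(labs == -10L)], "A")
    s <- prom$tata_rel_start[k]
    tata <- paste0(chars[which(labs == s):which(labs == s + 5L)],
                   collapse = "")
    expect_identical(tata, prom$tata_seq[k])
  }
})

test_that("leaderless fraction converges to the configured rate", {
  cfg <- simulationConfig(genome_length = 560000L, n_genes = 500L,
                          n_operons = 500L, leaderless_fraction = 0.12,
                          seed = 21)
  sim <- simulateGenome(cfg)
  u <- sim$truth$tss$utr_length[sim$truth$tss$category == "P"]
  frac <- mean(u <= 5L)
  ci <- stats::qbinom(c(0.025, 0.975), length(u), 0.12) / length(u)
  expect_gte(frac, ci[1L])
  expect_lte(frac, ci[2L])
})

test_that("TEX+ signal is confined to the TSS without background", {
  cfg <- simulationConfig(degradation_rate = 0, seed = 5,
                          n_antisense = 0L, n_intergenic = 0L,
                          n_genes = 5L, n_operons = 5L,
                          genome_length = 10000L)
  sim <- simulateGenome(cfg)
  prof <- simulateFivePrimeProfile(sim$truth, "TEX_PLUS", cfg)
  tssP <- sim$truth$tss
  for (st in c("+", "-")) {
    v <- strandSignal(prof, st)
    nz <- which(v > 0L)
    near <- vapply(nz, function(p)
      any(abs(tssP$position[tssP$strand == st] - p) <= 1L), logical(1L))
    expect_true(all(near))
  }
})

test_that("TEX- carries processed ends 20-30 nt downstream of the TSS", {
  cfg <- simulationConfig(degradation_rate = 0, seed = 5,
                          n_antisense = 0L, n_intergenic = 0L,
                          n_genes = 5L, n_operons = 5L,
                          tss_read_depth_mean = 200,
                          genome_length = 10000L)
  sim <- simulateGenome(cfg)
  prof <- simulateFivePrimeProfile(sim$truth, "TEX_MINUS", cfg)
  tssP <- sim$truth$tss[sim$truth$tss$category == "P", ]
  for (k in seq_len(nrow(tssP))) {
    p <- tssP$position[k]; st <- tssP$strand[k]
    v <- strandSignal(prof, st)
    win <- if (st == "+") v[(p + 20L):(p + 30L)] else v[(p - 30L):(p - 20L)]
    expect_gt(sum(win), 0L)
  }
})

test_that("total simulated 5'-end count matches the Poisson budget", {
  cfg <- simulationConfig(degradation_rate = 0, seed = 9,
                          tss_read_depth_mean = 50)
  sim <- simulateGenome(cfg)
  prof <- simulateFivePrimeProfile(sim$truth, "TEX_PLUS", cfg)
  n_tss <- nrow(sim$truth$tss)
  total <- sum(prof@fwd) + sum(prof@rev)
  mu <- n_tss * 50
  expect_lt(abs(total - mu), 4 * sqrt(mu))
})

test_that("expression profiles recover multipliers and respect zeros", {
  cfg <- simulationConfig(seed = 13, expression_background_rate = 0,
                          n_genes = 10L, n_operons = 10L,
                          n_antisense = 0L, n_intergenic = 0L,
                          n_structural = 0L, genome_length = 20000L)
  sim <- simulateGenome(cfg)
  # force a known multiplier pattern
  sim$truth$multipliers[, "MMC"] <- 1
  sim$truth$multipliers[1:3, "MMC"] <- 2
  sim$truth$multipliers[4, "MMC"] <- 0
  ref <- simulateExpressionProfile(sim$truth, "YPS", cfg)
  trt <- simulateExpressionProfile(sim$truth, "MMC", cfg)
  expect_error(simulateExpressionProfile(sim$truth, "XXX", cfg),
               "unknown condition")
  expr <- expressionTable(list(YPS = ref, MMC = trt), sim$annotation)
  fc <- foldChange(expr, "MMC", "YPS", min_fold = 2, pseudocount = 1)
  up_genes <- rownames(sim$truth$multipliers)[1:3]
  flat_genes <- rownames(sim$truth$multipliers)[5:10]
  # per-million scaling shifts all ratios by the library-composition
  # factor; the planted fold is recovered relative to unchanged genes
  baseline <- stats::median(fc$ratio[match(flat_genes, fc$gene_id)])
  expect_true(all(abs(fc$ratio[match(up_genes, fc$gene_id)] / baseline - 2)
                  < 0.3))
  zero_gene <- rownames(sim$truth$multipliers)[4L]
  gidx <- which(sim$truth$genes$gene_id == zero_gene)
  v <- strandSignal(trt, sim$truth$genes$strand[gidx])
  expect_identical(sum(v[sim$truth$genes$start[gidx]:
                         sim$truth$genes$end[gidx]]), 0)
  # off-transcript coverage is zero without background
  gr <- sim$annotation
  covered <- logical(cfg$genome_length)
  for (i in seq_along(gr))
    covered[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
  expect_identical(sum(strandSignal(ref, "+")[!covered]) +
                   sum(strandSignal(ref, "-")[!covered]), 0)
})
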