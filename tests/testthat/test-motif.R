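# Promoter windows, ZOOPS EM discovery, IUPAC scanning, composition, RBS.

test_that("promoter windows slice strand-oriented with no position 0", {
  #          1...5...10...15...20
  g <- paste0(rep("A", 97), collapse = "")
  g <- paste0(g, "CGT")  # length 100
  # + strand TSS at 100 with 2 up / 2 down: bases 98,99 + 100,101(truncated)
  tssP <- makeTss(data.frame(position = 50L, strand = "+"))
  win <- promoterWindows(tssP, g, upstream = 2L, downstream = 2L)
  expect_identical(nchar(win$sequence), 4L)
  expect_false(win$truncated)
  # explicit slicing check on a designed sequence
  g2 <- "AACGTTGCAT"
  winP <- promoterWindows(makeTss(data.frame(position = 5L, strand = "+")),
                          g2, upstream = 2L, downstream = 2L)
  expect_identical(winP$sequence, substr(g2, 3L, 6L))
  # - strand: reverse complement of genome[4..7] arranged -2,-1,+1,+2
  winM <- promoterWindows(makeTss(data.frame(position = 5L, strand = "-")),
                          g2, upstream = 2L, downstream = 2L)
  expect_identical(winM$sequence,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(g2, 4L, 7L)))))
  # boundary truncation is flagged
  winT <- promoterWindows(makeTss(data.frame(position = 3L, strand = "+")),
                          g2, upstream = 50L, downstream = 2L)
  expect_true(winT$truncated)
  expect_error(promoterWindows(makeTss(data.frame(position = 99L,
                                                  strand = "+")),
                               "ACGT"), "outside")
})

test_that("EM on degenerate input recovers the planted word exactly", {
  set.seed(1)
  n <- 50L
  flank <- function(k) paste0(sample(c("A", "C", "G", "T"), k,
                                     replace = TRUE), collapse = "")
  words <- vapply(1:n, function(i) paste0(flank(10L), "TTATAA", flank(10L)),
                  character(1L))
  # same offset in every window
  windows <- vapply(1:n, function(i)
    paste0(substr(words[i], 1L, 10L), "TTATAA",
           substr(words[i], 17L, 26L)), character(1L))
  res1 <- discoverMotif(windows, width = 6L, seed = 4L, pseudocount = 1e-6)
  expect_identical(motifConsensus(res1$model), "TTATAA")
  # invariant columns reach 2 bits as the pseudocount vanishes
  expect_true(all(informationContent(res1$model) > 1.95))
  # determinism across seeds on separable input
  res2 <- discoverMotif(windows, width = 6L, seed = 99L, pseudocount = 1e-6)
  expect_identical(motifConsensus(res2$model), motifConsensus(res1$model))
  # occurrences all at the planted offset
  expect_true(all(res1$occurrences$offset0 == 10L))
  expect_error(discoverMotif(windows, width = 50L), "width")
  expect_error(discoverMotif(windows[1:5], width = 6L), "at least 10")
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(8)
  windows <- vapply(1:40, function(i) {
    paste0(paste0(sample(c("A", "C", "G", "T"), sample(5:15, 1L),
                         replace = TRUE), collapse = ""), "GGTGAT",
           paste0(sample(c("A", "C", "G", "T"), 10L, replace = TRUE),
                  collapse = ""))
  }, character(1L))
  # pad to equal length
  W <- max(nchar(windows))
  windows <- vapply(windows, function(s)
    paste0(s, paste0(rep("A", W - nchar(s)), collapse = "")), character(1L),
    USE.NAMES = FALSE)
  res <- discoverMotif(windows, width = 6L, seed = 2L)
  expect_true(all(diff(res$logLik_trace) > -1e-6))
})

test_that("motif flank realignment yields fixed-width blocks", {
  cfg <- simulationConfig(seed = 31, n_genes = 15L, n_operons = 15L,
                          genome_length = 25000L)
  sim <- simulateGenome(cfg)
  prom <- sim$truth$promoters
  tss <- sim$truth$tss
  occ <- data.frame(position = tss$position, strand = tss$strand,
                    rel_start = prom$tata_rel_start)
  block <- realignMotifWindow(occ, sim$genome, width = 6L, up = 7L,
                              down = 21L)
  expect_true(all(nchar(block) == 7L + 6L + 21L))
  # motif columns of the block equal the planted TATA hexamers
  expect_identical(unname(substr(block, 8L, 13L)), prom$tata_seq)
  # an occurrence too close to the contig edge is dropped
  occ_edge <- data.frame(position = 5L, strand = "+", rel_start = -30L)
  expect_length(realignMotifWindow(occ_edge, sim$genome, width = 6L), 0L)
  # width-11 block arithmetic: 7 + 11 + 21 = 39
  occ1 <- occ[1L, , drop = FALSE]
  b39 <- realignMotifWindow(occ1, sim$genome, width = 11L)
  expect_identical(unname(nchar(b39)), 39L)
})

test_that("degenerate IUPAC matching agrees with set-membership brute force", {
  res <- scanIupac(c("GGTGAA", "GGCGAA"), "GGDGRD")
  expect_identical(res$has_match, c(TRUE, FALSE))
  expect_error(scanIupac("ACGT", "GGX"), "invalid IUPAC")
  set.seed(33)
  letters_iupac <- c("A", "C", "G", "T", "R", "Y", "W", "S", "D", "N")
  for (i in 1:200) {
    s <- paste0(sample(c("A", "C", "G", "T"), sample(8:40, 1L),
                       replace = TRUE), collapse = "")
    p <- paste0(sample(letters_iupac, sample(2:6, 1L), replace = TRUE),
                collapse = "")
    got <- scanIupac(s, p)$matches$offset0
    expect_identical(got, oracleIupacOffsets(s, p))
  }
})

test_that("TSS-proximal composition reports purine/pyrimidine preference", {
  # 20 TSSs, all with T at -1 and A at +1
  g <- paste0(rep("C", 500L), collapse = "")
  pos <- seq(50L, 430L, by = 20L)
  gch <- strsplit(g, "")[[1L]]
  gch[pos - 1L] <- "T"; gch[pos] <- "A"
  g <- paste0(gch, collapse = "")
  tss <- makeTss(data.frame(position = pos, strand = "+"))
  comp <- tssBaseComposition(tss, g)
  expect_equal(comp$all$purine_plus1, 100)
  expect_equal(comp$all$pyrimidine_minus1, 100)
  expect_true(all(abs(colSums(comp$all$fractions) - 1) < 1e-9))
})

test_that("planted purine rate at +1 is recovered within binomial bounds", {
  cfg <- simulationConfig(genome_length = 250000L, n_genes = 200L,
                          n_operons = 200L, purine_plus_one_rate = 0.93,
                          leaderless_fraction = 0, seed = 37)
  sim <- simulateGenome(cfg)
  tssP <- sim$truth$tss[sim$truth$tss$category == "P", ]
  tss <- makeTss(tssP[, c("position", "strand")])
  comp <- tssBaseComposition(tss, sim$genome)
  n <- nrow(tssP)
  ci <- stats::qbinom(c(0.025, 0.975), n, 0.93) / n * 100
  expect_gte(comp$all$purine_plus1, ci[1L])
  expect_lte(comp$all$purine_plus1, ci[2L])
})

test_that("RBS scanning flags planted Shine-Dalgarno motifs by class", {
  cfg <- simulationConfig(seed = 41, genome_length = 250000L,
                          n_genes = 200L, n_operons = 200L)
  sim <- simulateGenome(cfg)
  genes <- sim$truth$genes
  first <- genes[!is.na(genes$leader_class), ]
  records <- data.frame(gene_id = first$gene_id,
                        leader_class = first$leader_class)
  res <- scanRbs(records, sim$annotation, sim$genome)
  planted <- sim$truth$sd$gene_id
  got <- res$records
  # every gene with a planted SD is flagged at the planted offset
  sub <- got[got$gene_id %in% planted, ]
  expect_true(all(sub$rbs_found))
  # the reported offset is the 5'-most match; shifted degenerate matches
  # born of the G-rich SD context may precede the planted start, so the
  # offset is never downstream of it and usually equals it
  expect_true(all(sub$rbs_offset <= -9L))
  expect_gt(mean(sub$rbs_offset == -9L), 0.6)
  expect_identical(stats::median(sub$rbs_offset), -9)
  # leadered mRNAs carry the motif far more often than leaderless ones
  expect_gt(res$summary[["umRNA"]], 60)
  expect_lt(res$summary[["lmRNA"]], res$summary[["umRNA"]])
  # empty input gives an empty summary
  empty <- scanRbs(records[0, ], sim$annotation, sim$genome)
  expect_identical(nrow(empty$records), 0L)
})
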