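# Candidate detection, clustering, subdivision, selection, merging,
# classification, and operon assignment.

test_that("cross-library confirmation respects window and strand", {
  L <- 1000L
  texp <- makeProfile("TEX_PLUS", L, fwd_pos = 500L, fwd_count = 10L)
  # TEX- 5' end 3 nt away on the same strand: retained
  texm <- makeProfile("TEX_MINUS", L, fwd_pos = 503L, fwd_count = 4L)
  cand <- detectCandidates(texp, texm)
  expect_identical(cand$position, 500L)
  expect_identical(cand$count, 10L)
  # nearest TEX- end at +7: rejected
  texm7 <- makeProfile("TEX_MINUS", L, fwd_pos = 507L, fwd_count = 4L)
  expect_identical(nrow(detectCandidates(texp, texm7)), 0L)
  # TEX- support on the opposite strand only: rejected
  texmR <- makeProfile("TEX_MINUS", L, rev_pos = 500L, rev_count = 4L)
  expect_identical(nrow(detectCandidates(texp, texmR)), 0L)
})

test_that("widening the cross-library window never loses candidates", {
  set.seed(42)
  L <- 5000L
  texp <- makeProfile("TEX_PLUS", L, fwd_pos = sample(L, 40L),
                      fwd_count = sample(1:20, 40L, replace = TRUE))
  texm <- makeProfile("TEX_MINUS", L, fwd_pos = sample(L, 60L),
                      fwd_count = sample(1:5, 60L, replace = TRUE))
  n_prev <- -1L
  for (w in c(0L, 2L, 5L, 10L, 25L)) {
    n <- nrow(detectCandidates(texp, texm,
                               callingParams(cross_library_window = w)))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("single-linkage clustering chains gaps up to 150 nt", {
  cand <- data.frame(position = c(100L, 180L, 400L), count = c(5L, 5L, 5L))
  cl <- clusterCandidates(cand)
  expect_length(cl, 2L)
  expect_identical(cl[[1L]]$positions, c(100L, 180L))
  expect_identical(cl[[2L]]$positions, 400L)
  # 0,150,300 chain into one cluster through pairwise gaps of exactly 150
  cand2 <- data.frame(position = c(1L, 151L, 301L), count = c(1L, 1L, 1L))
  expect_length(clusterCandidates(cand2), 1L)
  # singleton
  single <- clusterCandidates(data.frame(position = 7L, count = 2L))
  expect_length(single, 1L)
  expect_identical(diff(range(single[[1L]]$positions)), 0L)
})

test_that("subdivision stops below the SD threshold and splits at the largest gap", {
  tight <- list(positions = c(1000L, 1003L), counts = c(20L, 5L))
  expect_equal(weightedSd(tight$positions, tight$counts),
               oracleWeightedSd(c(1000, 1003), c(20, 5)))
  expect_lt(weightedSd(tight$positions, tight$counts), 15)
  expect_length(subdivideCluster(tight), 1L)
  wide <- list(positions = c(1000L, 1100L), counts = c(10L, 10L))
  expect_equal(weightedSd(wide$positions, wide$counts), 50)
  subs <- subdivideCluster(wide)
  expect_length(subs, 2L)
  expect_identical(subs[[1L]]$positions, 1000L)
  singleton <- list(positions = 42L, counts = 3L)
  expect_identical(subdivideCluster(singleton), list(singleton))
  # read conservation: subdivision never loses reads
  set.seed(1)
  for (i in 1:25) {
    n <- sample(2:15, 1L)
    cl <- list(positions = sort(sample(2000L, n)),
               counts = sample(1:30, n, replace = TRUE))
    subs <- subdivideCluster(cl)
    expect_identical(sum(unlist(lapply(subs, `[[`, "counts"))),
                     sum(cl$counts))
  }
})

test_that("selection takes the max-read member, drops weak sub-clusters, and breaks ties 5'-most", {
  expect_identical(selectTss(list(positions = c(1000L, 1003L),
                                  counts = c(20L, 5L)))$position, 1000L)
  expect_null(selectTss(list(positions = c(900L, 905L), counts = c(1L, 1L))))
  tie <- list(positions = c(1000L, 1001L), counts = c(5L, 5L))
  expect_identical(selectTss(tie, strand = "+")$position, 1000L)
  expect_identical(selectTss(tie, strand = "-")$position, 1001L)
})

test_that("adjacent TSSs below the pairwise SD threshold are merged", {
  close_pair <- data.frame(position = c(1000L, 1008L), count = c(20L, 4L))
  expect_lt(oracleWeightedSd(close_pair$position, close_pair$count), 15)
  merged <- mergeAdjacentTss(close_pair)
  expect_identical(merged$position, 1000L)
  far_pair <- data.frame(position = c(1000L, 1100L), count = c(20L, 4L))
  expect_identical(nrow(mergeAdjacentTss(far_pair)), 2L)
  one <- data.frame(position = 1000L, count = 3L)
  expect_identical(mergeAdjacentTss(one), one)
})

test_that("raising min_reads never increases the number of called TSSs", {
  set.seed(7)
  cand <- data.frame(position = sort(sample(3000L, 30L)),
                     count = sample(1:10, 30L, replace = TRUE))
  n_prev <- Inf
  for (mr in c(1L, 3L, 5L, 10L)) {
    res <- archTSS:::.callStrand(cand, "+", callingParams(min_reads = mr))
    expect_lte(nrow(res), n_prev)
    n_prev <- nrow(res)
  }
})

test_that("curation matches literal rule application on random small strands", {
  set.seed(123)
  params <- callingParams()
  for (case in 1:300) {
    n <- sample(1:20, 1L)
    cand <- data.frame(position = sort(sample(2000L, n)),
                       count = sample(1:30, n, replace = TRUE))
    strand <- sample(c("+", "-"), 1L)
    got <- archTSS:::.callStrand(cand, strand, params)
    want <- oracleCallStrand(cand$position, cand$count, strand)
    expect_equal(got$position, want$position)
    expect_equal(got$count, want$count)
  }
})

test_that("classification assigns P/S/I/A/N exhaustively and exclusively", {
  ann <- makeAnn(data.frame(gene_id = c("g1", "g2"),
                            start = c(1000L, 3000L), end = c(2000L, 3900L),
                            strand = c("+", "+")))
  tss <- data.frame(
    position = c(880L, 940L, 960L, 1500L, 1600L, 2500L),
    strand =   c("+",  "+",  "+",  "+",  "-",  "+"),
    count =    c(100L, 40L,  60L,  70L,  9L,   8L))
  res <- classifyTss(tss, ann)
  cat_by_pos <- stats::setNames(res$category, GenomicRanges::start(res))
  # lone max-read upstream TSS is primary, distance -120
  expect_identical(unname(cat_by_pos["880"]), "P")
  expect_identical(res$distance_to_start[GenomicRanges::start(res) == 880L],
                   -120L)
  # 40 reads vs primary 100 is below the 50% rule: dropped entirely
  expect_false("940" %in% names(cat_by_pos))
  # 60 reads is retained as secondary
  expect_identical(unname(cat_by_pos["960"]), "S")
  # internal same-strand (70 >= 50% of 100 kept), antisense, intergenic
  expect_identical(unname(cat_by_pos["1500"]), "I")
  expect_identical(unname(cat_by_pos["1600"]), "A")
  expect_identical(unname(cat_by_pos["2500"]), "N")
  # partition: one category each, all categorized
  expect_false(anyNA(res$category))
  expect_identical(length(res), 5L)
})

test_that("P/S windows follow the parameterized -300..+50 bounds", {
  ann <- makeAnn(data.frame(gene_id = "g1", start = 5000L, end = 6000L,
                            strand = "-"))
  # reverse strand: upstream means higher coordinates
  tss_in <- data.frame(position = 6250L, strand = "-", count = 10L)
  res <- classifyTss(tss_in, ann)
  expect_identical(res$category, "P")
  expect_identical(res$distance_to_start, -250L)
  tss_out <- data.frame(position = 6350L, strand = "-", count = 10L)
  expect_identical(classifyTss(tss_out, ann)$category, "N")
  # +50 downstream limit on the gene's strand
  tss_dn <- data.frame(position = 5955L, strand = "-", count = 10L)
  expect_identical(classifyTss(tss_dn, ann)$category, "P")
})

test_that("operons are determined by their first gene's primary TSS", {
  ann <- makeAnn(data.frame(
    gene_id = c("a1", "a2", "a3", "b1", "b2", "c1", "d1", "d2"),
    start = c(1000L, 1500L, 2000L, 4000L, 4500L, 6000L, 8000L, 8500L),
    end = c(1400L, 1900L, 2400L, 4400L, 4900L, 6400L, 8400L, 8900L),
    strand = "+"))
  operons <- data.frame(
    operon_id = c("o1", "o1", "o1", "o2", "o2", "o3", "o4", "o4"),
    gene_id = c("a1", "a2", "a3", "b1", "b2", "c1", "d1", "d2"),
    pos_in_operon = c(1L, 2L, 3L, 1L, 2L, 1L, 1L, 2L))
  # o1 determined by P on a1; o2 has P only on internal member b2;
  # o3 determined; o4 undetermined
  tss <- makeTss(data.frame(position = c(950L, 4450L, 5950L),
                            strand = "+", category = "P",
                            gene_id = c("a1", "b2", "c1")))
  res <- assignOperonTss(tss, operons, ann)
  expect_identical(res$mapping$determined[res$mapping$operon_id == "o1"], TRUE)
  expect_identical(res$mapping$determined[res$mapping$operon_id == "o2"], FALSE)
  expect_identical(res$summary$n_determined, 2L)
  expect_equal(res$summary$pct_determined, 50)
  # multi-gene operons: o1 of {o1,o2,o4} determined
  expect_equal(res$summary$pct_multi_determined, 100 / 3)
  expect_error(assignOperonTss(tss, data.frame(operon_id = "ox",
                                               gene_id = "zz"), ann),
               "unknown gene")
})

test_that("end-to-end calling recovers planted primary TSSs", {
  cfg <- simulationConfig(seed = 17)
  sim <- simulateGenome(cfg)
  texp <- simulateFivePrimeProfile(sim$truth, "TEX_PLUS", cfg)
  texm <- simulateFivePrimeProfile(sim$truth, "TEX_MINUS", cfg)
  tss <- callTss(texp, texm, sim$annotation)
  truthP <- sim$truth$tss[sim$truth$tss$category == "P", ]
  called <- GenomicRanges::start(tss[tss$category == "P"])
  recall <- mean(vapply(truthP$position, function(p)
    any(abs(called - p) <= 2L), logical(1L)))
  precision <- mean(vapply(called, function(p)
    any(abs(truthP$position - p) <= 2L), logical(1L)))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
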