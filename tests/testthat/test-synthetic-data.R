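test_that("generators are pure functions of parameters and seed", {
  s1 <- generateGenomeAnnotation(nGenes = 15, repliconLength = 40000,
                                 seed = 5)
  s2 <- generateGenomeAnnotation(nGenes = 15, repliconLength = 40000,
                                 seed = 5)
  expect_equal(as.character(s1$genome), as.character(s2$genome))
  expect_equal(s1$truth$tss, s2$truth$tss)
  p1 <- simulateEndProfiles(s1, conditions = "H20", replicates = 1,
                            seed = 3)
  p2 <- simulateEndProfiles(s1, conditions = "H20", replicates = 1,
                            seed = 3)
  expect_equal(endCounts(p1[[1]])$score, endCounts(p2[[1]])$score)
  m1 <- simulateCountMatrix(nNull = 30, nC7 = 10, nC1 = 10, seed = 4)
  m2 <- simulateCountMatrix(nNull = 30, nC7 = 10, nC1 = 10, seed = 4)
  expect_equal(SummarizedExperiment::assay(m1$counts),
               SummarizedExperiment::assay(m2$counts))
  u1 <- generateStructuredUtrs(nPerClass = 5, seed = 6)
  u2 <- generateStructuredUtrs(nPerClass = 5, seed = 6)
  expect_equal(u1$structured, u2$structured)
})

test_that("generated annotation obeys its geometric invariants", {
  sim <- generateGenomeAnnotation(nGenes = 50, repliconLength = 100000,
                                  seed = 7)
  genes <- sim$genes
  expect_equal(length(genes), 50L)
  # >= 400 bp intergenic gaps irrespective of strand
  ord <- order(GenomicRanges::start(genes))
  gaps <- GenomicRanges::start(genes)[ord][-1] -
    GenomicRanges::end(genes)[ord][-50]
  expect_true(all(gaps >= 400))
  truth <- sim$truth$tss
  expect_true(all(truth$offset >= 20 & truth$offset <= 150))
  # planted TSSs sit at the recorded strand-aware offset
  scp <- genes$startCodonPos[match(truth$geneId, genes$geneId)]
  expect_equal(ifelse(truth$strand == "+", scp - truth$position,
                      truth$position - scp), truth$offset)
  # planted motifs are really in the sequence at their truth coordinates
  chrom <- sim$genome[["chr1"]]
  for (i in c(1, 25, 50)) {
    minus <- truth$strand[i] == "-"
    m10 <- truth$m10StartOffset[i]
    g0 <- if (minus) truth$position[i] - m10 - 5L else
      truth$position[i] + m10
    seg <- Biostrings::subseq(chrom, g0, g0 + 5L)
    if (minus) seg <- Biostrings::reverseComplement(seg)
    expect_equal(as.character(seg), "TATAAT")
    sdOff <- truth$sdStartOffset[i]
    s0 <- if (minus) scp[i] - sdOff - 5L else scp[i] + sdOff
    sd <- Biostrings::subseq(chrom, s0, s0 + 5L)
    if (minus) sd <- Biostrings::reverseComplement(sd)
    expect_equal(as.character(sd), "AGGAGG")
  }
  expect_error(generateGenomeAnnotation(nGenes = 100,
                                        repliconLength = 10000),
               "capacity")
})

test_that("about a fifth of genes belong to 2-4 gene operons", {
  sim <- generateGenomeAnnotation(nGenes = 200, repliconLength = 400000,
                                  seed = 12)
  sizes <- table(sim$operons$operonId)
  expect_true(all(sizes >= 2 & sizes <= 4))
  frac <- nrow(sim$operons) / 200
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.45)
  # members share a strand and are ordered 5'->3'
  for (op in unique(sim$operons$operonId)) {
    g <- sim$operons$geneId[sim$operons$operonId == op]
    sub <- sim$genes[match(g, sim$genes$geneId)]
    expect_equal(length(unique(as.character(
      GenomicRanges::strand(sub)))), 1L)
    scp <- sub$startCodonPos
    if (as.character(GenomicRanges::strand(sub))[1] == "+")
      expect_true(all(diff(scp) > 0))
    else expect_true(all(diff(scp) < 0))
  }
})

test_that("RPP+ spikes scale with depth x enrichment x library factor", {
  sim <- generateGenomeAnnotation(nGenes = 100, repliconLength = 220000,
                                  seed = 9)
  profs <- simulateEndProfiles(sim, conditions = "H20", depth = 50,
                               enrichment = 8, replicates = 1, seed = 9)
  f <- attr(profs, "libFactors")
  plus <- profs[["H20_r1_RPPp"]]
  gr <- endCounts(plus)
  atTss <- vapply(seq_len(nrow(sim$truth$tss)), function(i) {
    hit <- abs(GenomicRanges::start(gr) - sim$truth$tss$position[i]) <= 1 &
      as.character(GenomicRanges::strand(gr)) == sim$truth$tss$strand[i]
    sum(gr$score[hit])
  }, 0)
  # mean spike over 100 TSSs within Poisson error of 400 * library factor
  expected <- 50 * 8 * f[["H20_r1_RPPp"]]
  expect_equal(mean(atTss), expected, tolerance = 0.05)
})

test_that("unenriched profiles collapse TSS-caller recall", {
  sim <- generateGenomeAnnotation(nGenes = 40, repliconLength = 90000,
                                  seed = 15, enrichment = 1)
  profs <- simulateEndProfiles(sim, conditions = "H20", depth = 50,
                               enrichment = 1, replicates = 2, seed = 15)
  sf <- computeSizeFactors(binProfiles(profs))
  called <- callConditionTss(profs[grepl("RPPp", names(profs))],
                             profs[grepl("RPPm", names(profs))], sf)
  rec <- scoreTssRecovery(called, sim$truth$tss)$recall
  # the same geometry with 8x enrichment recovers essentially everything
  profs8 <- simulateEndProfiles(sim, conditions = "H20", depth = 50,
                                enrichment = 8, replicates = 2, seed = 15)
  sf8 <- computeSizeFactors(binProfiles(profs8))
  called8 <- callConditionTss(profs8[grepl("RPPp", names(profs8))],
                              profs8[grepl("RPPm", names(profs8))], sf8)
  rec8 <- scoreTssRecovery(called8, sim$truth$tss)$recall
  expect_gte(rec8, 0.9)
  expect_lt(rec, 0.5)
})

test_that("planted expression groups have their designed fold patterns", {
  m <- simulateCountMatrix(nNull = 150, nC7 = 40, nC1 = 40, nReps = 4,
                           dispersion = 0.05, seed = 21)
  counts <- SummarizedExperiment::assay(m$counts)
  cd <- SummarizedExperiment::colData(m$counts)
  norm <- sweep(counts, 2, m$sizeFactors, "/")
  l2fc <- function(cond) {
    log2((rowMeans(norm[, cd$condition == cond]) + 1) /
         (rowMeans(norm[, cd$condition == "H20"]) + 1))
  }
  fc <- sapply(c("A20", "H10", "A10"), l2fc)
  nullFc <- fc[m$groups == "null", ]
  expect_lt(mean(abs(nullFc)), 0.3)
  # C7-like: up in all three non-reference conditions
  expect_true(all(colMeans(fc[m$groups == "C7", ]) > 1.5))
  # C1-like: up in the autotrophic conditions only
  c1 <- colMeans(fc[m$groups == "C1", ])
  expect_gt(c1[["A20"]], 1.5)
  expect_gt(c1[["A10"]], 1.5)
  expect_lt(abs(c1[["H10"]]), 0.3)
})

test_that("structured UTRs fold far below their shuffles", {
  u <- generateStructuredUtrs(nPerClass = 10, stemLen = 6, loopLen = 4,
                              totalLen = 30, seed = 23)
  # planted perfect GC stem guarantees at least 6 GC pairs at -3 each
  mfes <- vapply(u$structured, function(s) foldMfe(s)$mfe, 0)
  expect_true(all(mfes <= -18))
  # shuffling preserves length and base multiset exactly
  for (i in 1:10) {
    expect_equal(nchar(u$shuffled[i]), nchar(u$structured[i]))
    expect_equal(sort(strsplit(u$shuffled[i], "")[[1]]),
                 sort(strsplit(u$structured[i], "")[[1]]))
  }
})

test_that("simulated data round-trips through the standard formats", {
  sim <- generateGenomeAnnotation(nGenes = 10, repliconLength = 30000,
                                  seed = 25)
  profs <- simulateEndProfiles(sim, conditions = "H20", replicates = 1,
                               seed = 25)
  dir <- tempfile()
  paths <- writeSimulatedData(sim, profs, dir)
  genome <- readGenome(paths$genome)
  expect_equal(as.character(genome), as.character(sim$genome))
  genes <- readAnnotation(paths$annotation, genome)
  expect_equal(GenomicRanges::start(genes), GenomicRanges::start(sim$genes))
  expect_equal(genes$startCodonPos, sim$genes$startCodonPos)
  row <- paths$manifest[1, ]
  back <- readBedgraphPair(row$plusBedgraph, row$minusBedgraph,
                           row$libraryId, row$condition, row$replicate,
                           row$treatment)
  orig <- endCounts(profs[[row$libraryId]])
  expect_equal(GenomicRanges::start(endCounts(back)),
               GenomicRanges::start(orig))
  expect_equal(endCounts(back)$score, orig$score)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$tss$position, sim$truth$tss$position)
})
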