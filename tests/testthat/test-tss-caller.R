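test_that("computeSizeFactors implements median-of-ratios", {
  expect_equal(unname(computeSizeFactors(rbind(c(5, 5), c(7, 7)))),
               c(1, 1))
  # hand evaluation: row geometric means sqrt(8), sqrt(72); both ratio
  # columns are (1/sqrt 2, sqrt 2)
  expect_equal(unname(computeSizeFactors(rbind(c(2, 4), c(6, 12)))),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # rows containing a zero are excluded from the median
  expect_equal(unname(computeSizeFactors(rbind(c(0, 4), c(6, 12)))),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_error(computeSizeFactors(rbind(c(0, 4), c(6, 0))),
               "normalization error")
})

test_that("size factors recover exact column scalings", {
  set.seed(11)
  base <- rpois(400, 50) + 1
  alpha <- c(0.5, 1, 2, 3.5)
  mat <- outer(base, alpha)
  sf <- computeSizeFactors(mat)
  # recovered up to a common constant: ratios match construction to 1e-9
  expect_equal(unname(sf / sf[2]), alpha / alpha[2], tolerance = 1e-9)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  mat <- matrix(rnbinom(600, mu = 80, size = 5), ncol = 4)
  mat[mat == 0] <- 1
  expect_equal(unname(computeSizeFactors(mat)),
               unname(DESeq2::estimateSizeFactorsForMatrix(mat)),
               tolerance = 1e-8)
})

test_that("normalizeProfile scales densities and preserves sparsity", {
  p <- makeProfile(c(100, 200), c(10, 4))
  n <- normalizeProfile(p, c(lib1 = 2))
  expect_equal(endCounts(n)$score, c(5, 2))
  expect_true(isNormalized(n))
  same <- normalizeProfile(p, c(lib1 = 1))
  expect_equal(endCounts(same)$score, endCounts(p)$score)
  expect_error(normalizeProfile(p, c(other = 2)), "no size factor")
})

test_that("detectCandidates applies the density floor", {
  p <- makeProfile(c(100, 200), c(7, 2))
  expect_equal(GenomicRanges::start(detectCandidates(p, 5)), 100L)
  expect_equal(length(detectCandidates(p, 0)), 2L)
  empty <- makeProfile(integer(), numeric())
  expect_equal(length(detectCandidates(empty, 5)), 0L)
})

test_that("clusterCandidates groups by 300-bp chains then pair SD < 15", {
  cand <- function(pos, dens, strand = "+") {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(pos, width = 1L),
                                 strand = strand, density = dens)
    sort(gr, ignore.strand = TRUE)
  }
  # gap 20 -> pair SD 10 < 15: one sub-cluster, highest density wins
  cl <- clusterCandidates(cand(c(100, 120), c(10, 50)))
  expect_equal(GenomicRanges::start(cl$representatives), 120L)
  expect_equal(cl$membership, c(1L, 1L))
  # gap 40 -> pair SD 20: two sub-clusters
  cl2 <- clusterCandidates(cand(c(100, 140), c(10, 50)))
  expect_equal(length(cl2$representatives), 2L)
  # single candidate is its own representative
  cl3 <- clusterCandidates(cand(150, 9))
  expect_equal(GenomicRanges::start(cl3$representatives), 150L)
  # density tie breaks to the most upstream (strand-aware)
  tiePlus <- clusterCandidates(cand(c(100, 110), c(5, 5)))
  expect_equal(GenomicRanges::start(tiePlus$representatives), 100L)
  tieMinus <- clusterCandidates(cand(c(100, 110), c(5, 5), "-"))
  expect_equal(GenomicRanges::start(tieMinus$representatives), 110L)
})

test_that("every candidate lands in exactly one sub-cluster", {
  set.seed(3)
  for (rep in 1:20) {
    pos <- sort(sample(1:5000, 40))
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(pos, width = 1L),
                                 strand = "+",
                                 density = runif(40, 1, 100))
    cl <- clusterCandidates(gr)
    expect_true(all(cl$membership >= 1L))
    expect_equal(sort(unique(cl$membership)),
                 seq_len(length(cl$representatives)))
    expect_true(all(GenomicRanges::start(cl$representatives) %in% pos))
  }
})

test_that("enrichmentRatio uses pseudocounted density ratio", {
  plus <- makeProfile(100, 100)
  minus <- makeProfile(100, 10, treatment = "RPP-")
  expect_equal(enrichmentRatio(100, "chr1", "+", plus, minus), 101 / 11)
  plus2 <- makeProfile(100, 20)
  minus2 <- makeProfile(100, 15, treatment = "RPP-")
  expect_equal(enrichmentRatio(100, "chr1", "+", plus2, minus2), 1.3125)
  # zero background
  plus3 <- makeProfile(100, 5)
  minus3 <- makeProfile(500, 2, treatment = "RPP-")
  expect_equal(enrichmentRatio(100, "chr1", "+", plus3, minus3), 6)
})

test_that("callConditionTss enforces enrichment and replicate consensus", {
  sf <- c(p1 = 1, m1 = 1, p2 = 1, m2 = 1)
  mkP <- function(id, rep, pos, score)
    makeProfile(pos, score, libraryId = id, replicate = rep)
  mkM <- function(id, rep, pos = 1, score = 0.1)
    makeProfile(pos, score, libraryId = id, replicate = rep,
                treatment = "RPP-")
  # representatives at 100 and 103: one TSS at the higher-density position
  tss <- callConditionTss(list(mkP("p1", 1, 100, 50),
                               mkP("p2", 2, 103, 80)),
                          list(mkM("m1", 1), mkM("m2", 2)), sf)
  expect_equal(length(tss), 1L)
  expect_equal(tssTable(tss)$position, 103L)
  expect_equal(tssTable(tss)$density, 80)
  # 10 bp apart: not reproducible
  none <- callConditionTss(list(mkP("p1", 1, 100, 50),
                                mkP("p2", 2, 110, 80)),
                           list(mkM("m1", 1), mkM("m2", 2)), sf)
  expect_equal(length(none), 0L)
  # enrichment below twofold in one replicate kills the site
  weak <- callConditionTss(list(mkP("p1", 1, 100, 50),
                                mkP("p2", 2, 100, 12)),
                           list(mkM("m1", 1),
                                mkM("m2", 2, pos = 100, score = 10)), sf)
  expect_equal(length(weak), 0L)
  # single replicate allowed with a warning
  expect_warning(
    one <- callConditionTss(list(mkP("p1", 1, 100, 50)),
                            list(mkM("m1", 1)), sf),
    "single replicate")
  expect_equal(length(one), 1L)
  expect_error(callConditionTss(list(), list(), sf), "partner")
})

test_that("mergeTssSets absorbs within +/-4 bp and labels scope", {
  a <- makeTss(100, "+", 50, conditions = "A")
  b <- makeTss(103, "+", 80, conditions = "B")
  merged <- mergeTssSets(list(a, b))
  expect_equal(length(merged), 1L)
  tab <- tssTable(merged)
  expect_equal(tab$position, 103L)
  expect_equal(tab$conditions, "A,B")
  expect_equal(tab$scope, "constitutive")  # both of the 2 input conditions
  merged3 <- mergeTssSets(list(a, b), nConditions = 3)
  expect_equal(tssTable(merged3)$scope, "conditional")

  # chain 100/104/108: the density seed absorbs both neighbours
  chain <- makeTss(c(100, 104, 108), "+", c(10, 50, 20))
  m <- mergeTssSets(list(chain))
  expect_equal(length(m), 1L)
  expect_equal(tssTable(m)$position, 104L)

  # different strands never merge
  twoStrands <- mergeTssSets(list(makeTss(100, "+", 5),
                                  makeTss(100, "-", 7)))
  expect_equal(length(twoStrands), 2L)
})

test_that("mergeTssSets is idempotent and never grows", {
  set.seed(8)
  for (rep in 1:10) {
    pos <- sample(1:2000, 30)
    s <- makeTss(pos, "+", runif(30, 1, 100),
                 conditions = sample(c("A", "B"), 30, replace = TRUE))
    m1 <- mergeTssSets(list(s), nConditions = 2)
    expect_lte(length(m1), length(s))
    m2 <- mergeTssSets(list(m1), nConditions = 2)
    expect_equal(tssTable(m2)$position, tssTable(m1)$position)
    expect_equal(tssTable(m2)$conditions, tssTable(m1)$conditions)
  }
})

test_that("binProfiles sums raw counts per 200-bp bin and library", {
  p1 <- makeProfile(c(100, 150, 300), c(5, 3, 2), libraryId = "a")
  p2 <- makeProfile(c(120, 310), c(7, 4), libraryId = "b")
  mat <- binProfiles(list(p1, p2), binSize = 200)
  expect_equal(colnames(mat), c("a", "b"))
  expect_equal(mat["chr1:0", ], c(a = 8, b = 7))
  expect_equal(mat["chr1:1", ], c(a = 2, b = 4))
})
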