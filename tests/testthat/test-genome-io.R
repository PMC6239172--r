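test_that("readGenome normalizes case and U and enforces format", {
  g <- readGenome(writeTempFasta(c(">chr", "ACGT")))
  expect_equal(names(g), "chr")
  expect_equal(as.character(g[["chr"]]), "ACGT")
  expect_equal(Biostrings::width(g), 4L)

  g2 <- readGenome(writeTempFasta(c(">a", "acgu")))
  expect_equal(as.character(g2[["a"]]), "ACGT")

  expect_error(readGenome(writeTempFasta(c(">a", "AC", ">a", "GG"))),
               "duplicate")
  expect_error(readGenome(writeTempFasta(c(">a", "ACXT"))), "non-IUPAC")
  expect_error(readGenome(writeTempFasta(character())), "empty")
})

test_that("readAnnotation converts coordinates and start codons per strand", {
  genome <- readGenome(writeTempFasta(c(">chr",
    paste(rep("ACGT", 1000), collapse = ""))))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\t.\tCDS\t1000\t2000\t.\t+\t0\tID=g1",
               "chr\t.\tCDS\t2500\t3000\t.\t-\t0\tID=g2"), gff)
  genes <- readAnnotation(gff, genome)
  expect_equal(length(genes), 2L)
  g1 <- genes[genes$geneId == "g1"]
  expect_equal(GenomicRanges::start(g1), 1000L)
  expect_equal(GenomicRanges::end(g1), 2000L)
  expect_equal(g1$startCodonPos, 1000L)
  g2 <- genes[genes$geneId == "g2"]
  expect_equal(g2$startCodonPos, 3000L)
})

test_that("readAnnotation rejects bad records with their index", {
  genome <- readGenome(writeTempFasta(c(">chr",
    paste(rep("ACGT", 250), collapse = ""))))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\t.\tCDS\t10\t2000\t.\t+\t0\tID=g1"), gff)
  expect_error(readAnnotation(gff, genome), "bounds")
  writeLines(c("##gff-version 3",
               "plasmid\t.\tCDS\t10\t20\t.\t+\t0\tID=g1"), gff)
  expect_error(readAnnotation(gff, genome), "unknown replicon")
  writeLines(c("##gff-version 3",
               "chr\t.\tCDS\t10\t20\t.\t+\t0\tNote=x"), gff)
  expect_error(readAnnotation(gff, genome), "ID")
})

test_that("annotation write/read round-trips coordinates exactly", {
  genes <- makeGenes(c(100, 500), c(300, 800), c("+", "-"),
                     c("gA", "gB"), seqlen = 1000)
  path <- tempfile(fileext = ".gff3")
  writeAnnotation(genes, path)
  genome <- readGenome(writeTempFasta(c(">chr1",
    paste(rep("ACGT", 250), collapse = ""))))
  back <- readAnnotation(path, genome)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(genes))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(genes))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(genes)))
  expect_equal(back$startCodonPos, genes$startCodonPos)
})

test_that("readBedgraphPair expands intervals to per-position counts", {
  # bedGraph is 0-based half-open: [100, 101) is 1-based position 101
  bg <- writeTempBedgraphs("chr\t100\t101\t7")
  p <- readBedgraphPair(bg$plus, bg$minus, "lib1")
  gr <- endCounts(p)
  expect_equal(length(gr), 1L)
  expect_equal(GenomicRanges::start(gr), 101L)
  expect_equal(gr$score, 7)
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")

  bg2 <- writeTempBedgraphs("chr\t100\t103\t2")
  gr2 <- endCounts(readBedgraphPair(bg2$plus, bg2$minus, "lib1"))
  expect_equal(GenomicRanges::start(gr2), c(101L, 102L, 103L))
  expect_equal(gr2$score, rep(2, 3))

  bg3 <- writeTempBedgraphs("chr\t100\t101\t-1")
  expect_error(readBedgraphPair(bg3$plus, bg3$minus, "lib1"), "negative")

  bg4 <- writeTempBedgraphs(c("chr\t100\t103\t2", "chr\t102\t104\t3"))
  expect_error(readBedgraphPair(bg4$plus, bg4$minus, "lib1"),
               "overlapping")

  bg5 <- writeTempBedgraphs("chr\t100\t102\t0")
  expect_equal(length(endCounts(readBedgraphPair(bg5$plus, bg5$minus,
                                                 "l"))), 0L)
})

test_that("bedGraph write/read round-trips an EndProfile", {
  p <- makeProfile(c(10, 11, 12, 50), c(3, 3, 5, 2))
  m <- makeProfile(c(20, 30), c(4, 1), strand = "-", treatment = "RPP-")
  both <- EndProfile("lib1", "H20", 1, "RPP+",
                     c(endCounts(p), endCounts(m)))
  prefix <- tempfile()
  writeBedgraphPair(both, prefix)
  back <- readBedgraphPair(paste0(prefix, ".plus.bedgraph"),
                           paste0(prefix, ".minus.bedgraph"), "lib1")
  expect_equal(GenomicRanges::start(endCounts(back)),
               GenomicRanges::start(endCounts(both)))
  expect_equal(endCounts(back)$score, endCounts(both)$score)
  expect_equal(as.character(GenomicRanges::strand(endCounts(back))),
               as.character(GenomicRanges::strand(endCounts(both))))
})

test_that("EndProfile enforces sparsity, strand and bounds", {
  expect_error(makeProfile(10, 0), NA)  # zero dropped silently
  expect_equal(length(endCounts(makeProfile(c(10, 20), c(0, 5)))), 1L)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 50),
                               strand = "+", score = 1)
  expect_error(EndProfile("l", "c", 1, "RPP+", gr,
                          seqlengths = c(chr1 = 40)), "bounds")
  expect_error(EndProfile("l", "c", 1, "bad", gr), "treatment")
})

test_that("writeTssOutputs reports 1-based TSV, 0-based BED, JSON counts", {
  tss <- makeTss(950, "+", 100)
  tss <- classifyTss(tss, makeGenes(1000, 2000, "+", "g1"))
  prefix <- tempfile()
  paths <- writeTssOutputs(tss, prefix)
  tsv <- read.table(paths[["tsv"]], header = TRUE, sep = "\t")
  expect_equal(tsv$position, 950L)
  expect_equal(tsv$category, "P")
  bed <- read.table(paths[["bed"]], sep = "\t")
  expect_equal(bed$V2, 949L)          # chromStart is 0-based
  expect_equal(bed$V3, 950L)
  expect_equal(bed$V4, "P")
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$P, 1L)
  expect_equal(js$total, 1L)

  # record counts in TSV and BED always equal the TSS set size
  two <- makeTss(c(100, 5000), c("+", "-"), c(10, 20))
  paths2 <- writeTssOutputs(two, tempfile())
  expect_equal(nrow(read.table(paths2[["tsv"]], header = TRUE,
                               sep = "\t")), 2L)
  expect_equal(nrow(read.table(paths2[["bed"]], sep = "\t")), 2L)

  empty <- TssSet()
  paths3 <- writeTssOutputs(empty, tempfile())
  expect_equal(nrow(read.table(paths3[["tsv"]], header = TRUE,
                               sep = "\t")), 0L)
  expect_equal(file.size(paths3[["bed"]]), 0)
  js3 <- jsonlite::read_json(paths3[["json"]])
  expect_true(all(unlist(js3[c("P", "S", "I", "A", "N")]) == 0))
})

test_that("TSS table TSV round-trips through readTssTable", {
  tss <- makeTss(c(120, 4000), c("+", "-"), c(50, 9), "A10,H20")
  paths <- writeTssOutputs(tss, tempfile())
  back <- readTssTable(paths[["tsv"]])
  expect_equal(tssTable(back)$position, tssTable(tss)$position)
  expect_equal(tssTable(back)$conditions, tssTable(tss)$conditions)
})
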