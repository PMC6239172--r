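# Small in-code fixtures shared across test files.

writeTempFasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

writeTempBedgraphs <- function(plusLines, minusLines = character()) {
  plus <- tempfile(fileext = ".plus.bedgraph")
  minus <- tempfile(fileext = ".minus.bedgraph")
  writeLines(plusLines, plus)
  writeLines(minusLines, minus)
  list(plus = plus, minus = minus)
}

# a width-1 profile from position/score vectors (1-based positions)
makeProfile <- function(pos, score, strand = "+", libraryId = "lib1",
                        condition = "H20", replicate = 1,
                        treatment = "RPP+", seqname = "chr1") {
  gr <- if (length(pos))
    GenomicRanges::GRanges(seqname, IRanges::IRanges(pos, width = 1L),
                           strand = strand, score = score)
  else {
    g <- GenomicRanges::GRanges()
    S4Vectors::mcols(g)$score <- numeric()
    g
  }
  EndProfile(libraryId, condition, replicate, treatment, gr)
}

# minimal gene GRanges in the package's annotation layout
makeGenes <- function(start, end, strand, geneId,
                      seqname = "chr1", seqlen = 1e6) {
  gr <- GenomicRanges::GRanges(seqname, IRanges::IRanges(start, end),
                               strand = strand, geneId = geneId,
                               kind = "CDS",
                               startCodonPos = ifelse(strand == "+",
                                                      start, end))
  names(gr) <- geneId
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(seqlen, seqname)
  gr
}

makeTss <- function(pos, strand, density, conditions = "H20",
                    seqname = "chr1") {
  gr <- GenomicRanges::GRanges(seqname, IRanges::IRanges(pos, width = 1L),
                               strand = strand, density = density,
                               enrichment = 10, conditions = conditions)
  TssSet(gr)
}
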