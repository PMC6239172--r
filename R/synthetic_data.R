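#' Generate a synthetic genome with annotation, promoters and truth
#'
#' Builds a uniform-random replicon carrying `nGenes` genes separated by at
#' least 400 bp of intergenic DNA on either strand, each with a planted
#' true TSS 20-150 bp upstream of its start codon. Promoter elements are
#' embedded relative to each TSS: a `TATAAT` -10 box whose hexamer sits in
#' offsets `[-20, -5]`, a `TTGACA` -35 box separated from it by a 17+/-1 bp
#' spacer, and an `AGGAGG` Shine-Dalgarno motif starting 12+/-2 nt before
#' the start codon. Start codons are drawn as ATG/TTG/GTG (86/8/6%).
#' About 20% of genes are grouped into 2-4-gene same-strand operons.
#' Deterministic given `seed`.
#'
#' @param nGenes number of genes.
#' @param repliconLength replicon length in bp.
#' @param seed RNG seed.
#' @param enrichment RPP+/RPP- enrichment factor recorded for every
#'   planted TSS (consumed by [simulateEndProfiles()]).
#' @return list with `genome` (`DNAStringSet`), `genes` (`GRanges` as from
#'   [readAnnotation()]), `operons` (`data.frame`: `operonId`, `geneId`,
#'   `order`) and `truth` (list: `tss` data.frame with planted positions,
#'   offsets and element coordinates; `params`).
#' @export
generateGenomeAnnotation <- function(nGenes = 60, repliconLength = 120000,
                                     seed = 1, enrichment = 8) {
  set.seed(seed)
  minGap <- 400L
  lens <- sample(400:1200, nGenes, replace = TRUE)
  if (sum(lens) + (nGenes + 1L) * (minGap + 200L) > repliconLength)
    stop("capacity exceeded: genes x mean length does not fit the replicon")
  seqChars <- sample(c("A", "C", "G", "T"), repliconLength, replace = TRUE)
  # operon blocks: ~20% of genes in 2-4-gene operons
  blocks <- list()
  i <- 1L
  while (i <= nGenes) {
    size <- if (stats::runif(1) < 0.08) min(sample(2:4, 1L), nGenes - i + 1L)
            else 1L
    blocks[[length(blocks) + 1L]] <- seq.int(i, i + size - 1L)
    i <- i + size
  }
  strandOf <- character(nGenes)
  start <- integer(nGenes); end <- integer(nGenes)
  cursor <- minGap + sample(0:200, 1L)
  for (b in blocks) {
    s <- sample(c("+", "-"), 1L)
    for (g in b) {
      strandOf[g] <- s
      start[g] <- cursor + 1L
      end[g] <- start[g] + lens[g] - 1L
      cursor <- end[g] + minGap + sample(0:200, 1L)
    }
  }
  if (max(end) + minGap > repliconLength)
    stop("capacity exceeded: genes x mean length does not fit the replicon")
  scp <- ifelse(strandOf == "+", start, end)
  offset <- sample(20:150, nGenes, replace = TRUE)
  tssPos <- ifelse(strandOf == "+", scp - offset, scp + offset)
  m10Start <- -sample(10:20, nGenes, replace = TRUE)   # in [-20,-10]
  spacer <- sample(16:18, nGenes, replace = TRUE)
  m35Start <- m10Start - spacer - 6L
  sdStart <- -12L + sample(-2:2, nGenes, replace = TRUE)
  codons <- sample(c("ATG", "TTG", "GTG"), nGenes, replace = TRUE,
                   prob = c(0.86, 0.08, 0.06))
  plant <- function(chars, genomicStart, motif, minus) {
    b <- strsplit(motif, "")[[1L]]
    if (minus) b <- rev(chartr("ACGT", "TGCA", b))
    chars[genomicStart:(genomicStart + length(b) - 1L)] <- b
    chars
  }
  for (g in seq_len(nGenes)) {
    minus <- strandOf[g] == "-"
    atTss <- function(off) if (minus) tssPos[g] - off - 5L else
      tssPos[g] + off
    atScp <- function(off) if (minus) scp[g] - off - 5L else scp[g] + off
    seqChars <- plant(seqChars, atTss(m10Start[g]), "TATAAT", minus)
    seqChars <- plant(seqChars, atTss(m35Start[g]), "TTGACA", minus)
    seqChars <- plant(seqChars, atScp(sdStart[g]), "AGGAGG", minus)
    cStart <- if (minus) scp[g] - 2L else scp[g]
    seqChars <- plant(seqChars, cStart, codons[g], minus)
  }
  genome <- Biostrings::DNAStringSet(paste(seqChars, collapse = ""))
  names(genome) <- "chr1"
  geneIds <- sprintf("g%03d", seq_len(nGenes))
  genes <- GRanges("chr1", IRanges(start, end), strand = strandOf,
                   geneId = geneIds, kind = "CDS", startCodonPos = scp)
  names(genes) <- geneIds
  GenomeInfoDb::seqlengths(genes) <- c(chr1 = repliconLength)
  operonRows <- list()
  opN <- 0L
  for (b in blocks) {
    if (length(b) < 2L) next
    opN <- opN + 1L
    ord <- if (strandOf[b[1L]] == "-") rev(b) else b
    operonRows[[opN]] <- data.frame(
      operonId = sprintf("op%03d", opN),
      geneId = geneIds[ord], order = seq_along(ord),
      stringsAsFactors = FALSE)
  }
  operons <- if (opN) do.call(rbind, operonRows) else
    data.frame(operonId = character(), geneId = character(),
               order = integer())
  truth <- list(
    tss = data.frame(geneId = geneIds, position = tssPos,
                     strand = strandOf, offset = offset,
                     category = "P", enrichment = enrichment,
                     m10StartOffset = m10Start,
                     m35StartOffset = m35Start,
                     sdStartOffset = sdStart,
                     startCodon = codons, stringsAsFactors = FALSE),
    params = list(nGenes = nGenes, repliconLength = repliconLength,
                  seed = seed, enrichment = enrichment))
  list(genome = genome, genes = genes, operons = operons, truth = truth)
}

#' Simulate stranded 5'-end profiles for RPP+/RPP- libraries
#'
#' Emulates dRNA-seq 5'-end behaviour: RPP- libraries carry a processed-end
#' background (Poisson counts at positions scattered through transcribed
#' spans) plus `Poisson(depth)` primary signal at each true TSS; RPP+
#' libraries carry `Poisson(depth * enrichment)` at each true TSS with
#' single-base positional jitter (80% exact, 10% each +/-1 bp) over a
#' halved background leak. Every library's Poisson means are multiplied by
#' a library-specific depth factor drawn from `[0.5, 1.5]`, which the
#' size-factor normalization must undo. Independent draws per replicate
#' and condition; deterministic given `seed`.
#'
#' @param sim output of [generateGenomeAnnotation()].
#' @param conditions condition labels.
#' @param depth expected RPP- primary count at a true TSS.
#' @param enrichment RPP+ over RPP- enrichment factor (> 1 for signal).
#' @param replicates biological replicates per condition.
#' @param lambdaBg background Poisson mean per occupied position.
#' @param bgFraction fraction of span positions carrying background.
#' @param seed RNG seed.
#' @return list of [EndProfile-class], named by library id
#'   (`<condition>_r<rep>_<RPPp|RPPm>`), with the drawn per-library depth
#'   factors in `attr(, "libFactors")`.
#' @export
simulateEndProfiles <- function(sim, conditions = c("H20", "A20", "H10",
                                                    "A10"),
                                depth = 50, enrichment = 8,
                                replicates = 2, lambdaBg = 2,
                                bgFraction = 0.05, seed = 1) {
  set.seed(seed)
  truth <- sim$truth$tss
  genes <- sim$genes
  L <- Biostrings::width(sim$genome)[1L]
  spanStart <- pmin(truth$position, start(genes))
  spanEnd <- pmax(truth$position, end(genes))
  profiles <- list()
  libFactors <- numeric()
  for (cond in conditions) for (r in seq_len(replicates))
    for (trt in c("RPP+", "RPP-")) {
      fLib <- stats::runif(1, 0.5, 1.5)
      pos <- integer(); strd <- character(); score <- integer()
      for (g in seq_len(nrow(truth))) {
        span <- spanStart[g]:spanEnd[g]
        nbg <- max(1L, round(bgFraction * length(span)))
        bgPos <- sample(span, nbg)
        lam <- if (trt == "RPP+") lambdaBg * 0.5 else lambdaBg
        bgCounts <- stats::rpois(nbg, lam * fLib)
        tssLam <- if (trt == "RPP+") depth * enrichment else depth
        tssN <- stats::rpois(1L, tssLam * fLib)
        if (trt == "RPP+" && tssN > 0) {
          jit <- stats::rmultinom(1L, tssN, c(0.8, 0.1, 0.1))[, 1L]
          tssPos <- truth$position[g] + c(0L, -1L, 1L)
          keep <- jit > 0
          pos <- c(pos, bgPos, tssPos[keep])
          score <- c(score, bgCounts, jit[keep])
          strd <- c(strd, rep(truth$strand[g], nbg + sum(keep)))
        } else {
          pos <- c(pos, bgPos, truth$position[g])
          score <- c(score, bgCounts, tssN)
          strd <- c(strd, rep(truth$strand[g], nbg + 1L))
        }
      }
      keep <- score > 0 & pos >= 1L & pos <= L
      df <- data.frame(pos = pos[keep], strd = strd[keep],
                       score = score[keep])
      agg <- stats::aggregate(score ~ pos + strd, df, sum)
      gr <- GRanges("chr1", IRanges(agg$pos, width = 1L),
                    strand = agg$strd, score = agg$score)
      GenomeInfoDb::seqlengths(gr) <- c(chr1 = L)
      id <- paste0(cond, "_r", r, "_",
                   if (trt == "RPP+") "RPPp" else "RPPm")
      profiles[[id]] <- EndProfile(id, cond, r, trt, gr)
      libFactors[[id]] <- fLib
    }
  attr(profiles, "libFactors") <- libFactors
  profiles
}

#' Simulate a condition x replicate RNA-seq count matrix
#'
#' Negative-binomial counts with log-normal gene base means and planted
#' expression groups: `C7-like` genes are up-regulated (default 4-fold) in
#' all three non-reference conditions, `C1-like` genes only in the
#' autotrophic conditions, and `null` genes are flat. Library size factors
#' are drawn from `[0.5, 2]`. Deterministic given `seed`.
#'
#' @param nNull,nC7,nC1 genes per planted group.
#' @param conditions condition labels; the first is the reference. With the
#'   default `H20, A20, H10, A10` labels the autotrophic set is
#'   `A20`/`A10`.
#' @param nReps replicates per condition.
#' @param dispersion NB dispersion (`size = 1/dispersion`).
#' @param foldChange planted fold change.
#' @param seed RNG seed.
#' @return list with `counts` (a `SummarizedExperiment`, assay `counts`,
#'   `colData` columns `condition`, `replicate`), `groups` (named character
#'   vector: planted group per gene) and `sizeFactors` (true library depth
#'   factors).
#' @export
simulateCountMatrix <- function(nNull = 200, nC7 = 60, nC1 = 60,
                                conditions = c("H20", "A20", "H10", "A10"),
                                nReps = 4, dispersion = 0.05,
                                foldChange = 4, seed = 1) {
  set.seed(seed)
  nGenes <- nNull + nC7 + nC1
  groups <- rep(c("null", "C7", "C1"), c(nNull, nC7, nC1))
  geneIds <- sprintf("gene%04d", seq_len(nGenes))
  names(groups) <- geneIds
  base <- stats::rlnorm(nGenes, meanlog = log(100), sdlog = 1)
  ref <- conditions[1L]
  auto <- grep("^A", conditions, value = TRUE)
  fcMat <- matrix(1, nGenes, length(conditions),
                  dimnames = list(geneIds, conditions))
  fcMat[groups == "C7", setdiff(conditions, ref)] <- foldChange
  fcMat[groups == "C1", intersect(auto, setdiff(conditions, ref))] <-
    foldChange
  libIds <- as.vector(outer(conditions, seq_len(nReps),
                            function(c, r) paste0(c, "_r", r)))
  sf <- stats::runif(length(libIds), 0.5, 2)
  names(sf) <- libIds
  counts <- matrix(0L, nGenes, length(libIds),
                   dimnames = list(geneIds, libIds))
  for (j in seq_along(libIds)) {
    cond <- sub("_r\\d+$", "", libIds[j])
    mu <- base * fcMat[, cond] * sf[j]
    counts[, j] <- stats::rnbinom(nGenes, mu = mu, size = 1 / dispersion)
  }
  colData <- S4Vectors::DataFrame(
    condition = sub("_r\\d+$", "", libIds),
    replicate = as.integer(sub("^.*_r", "", libIds)),
    row.names = libIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = colData)
  list(counts = se, groups = groups, sizeFactors = sf)
}

#' Generate structured and shuffled 5'-UTR sequence sets
#'
#' The structured class carries a planted perfect hairpin: a GC-only stem
#' of `stemLen` bp, a loop of `loopLen` random bases and the reverse
#' complement of the stem, embedded in random flanks up to `totalLen`.
#' The unstructured class contains a mononucleotide shuffle of each
#' structured sequence, preserving length and base composition exactly.
#'
#' @param nPerClass sequences per class.
#' @param stemLen stem length in bp (>= 3).
#' @param loopLen loop length in nt (>= 3).
#' @param totalLen total sequence length.
#' @param seed RNG seed.
#' @return list with `structured` and `shuffled` (character vectors of RNA
#'   sequences) and `classes` (label vector for the concatenation).
#' @export
generateStructuredUtrs <- function(nPerClass = 100, stemLen = 6,
                                   loopLen = 4, totalLen = 30, seed = 1) {
  stopifnot(stemLen >= 3, loopLen >= 3)
  core <- 2L * stemLen + loopLen
  stopifnot(totalLen >= core)
  set.seed(seed)
  rna <- c("A", "C", "G", "U")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  structured <- character(nPerClass)
  shuffled <- character(nPerClass)
  for (i in seq_len(nPerClass)) {
    stem <- sample(c("G", "C"), stemLen, replace = TRUE)
    loop <- sample(rna, loopLen, replace = TRUE)
    nFlank <- totalLen - core
    nLeft <- sample(0:nFlank, 1L)
    flankL <- sample(rna, nLeft, replace = TRUE)
    flankR <- sample(rna, nFlank - nLeft, replace = TRUE)
    chars <- c(flankL, stem, loop, rev(unname(comp[stem])), flankR)
    structured[i] <- paste(chars, collapse = "")
    shuffled[i] <- paste(sample(chars), collapse = "")
  }
  list(structured = structured, shuffled = shuffled,
       classes = rep(c("structured", "shuffled"), each = nPerClass))
}

#' Build the classification archetype genome
#'
#' A small deterministic genome containing one unambiguous instance of
#' each TSS category relation -- primary (P), secondary (S), internal (I),
#' antisense (A), intergenic (N) -- plus a divergent-gene tie case whose
#' planted winner is the lexicographically smaller gene id. Used to verify
#' [classifyTss()] against planted truth.
#'
#' @param seed RNG seed for the background sequence.
#' @return list with `genome`, `genes`, `tss` (an unclassified
#'   [TssSet-class]) and `expected` (`data.frame`: `position`, `category`,
#'   `geneId`).
#' @export
generateCategoryArchetypes <- function(seed = 1) {
  set.seed(seed)
  L <- 12000L
  genome <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  names(genome) <- "chr1"
  genes <- GRanges("chr1",
                   IRanges(c(1000, 4000, 8000, 8000),
                           c(2000, 5000, 9000, 9000)),
                   strand = c("+", "+", "+", "-"),
                   geneId = c("gA", "gB", "gC", "gD"),
                   kind = "CDS",
                   startCodonPos = c(1000, 4000, 8000, 9000))
  genes <- genes[1:3]
  # tandem pair with overlapping windows: gV (+, start codon 10600) and
  # gW (+, start codon 10800); a TSS at 10700 is 100 bp from both start
  # codons -> tie, resolved to the lexicographically smaller id gV
  tie <- GRanges("chr1", IRanges(c(10600, 10800), c(10690, 11300)),
                 strand = c("+", "+"),
                 geneId = c("gV", "gW"), kind = "CDS",
                 startCodonPos = c(10600, 10800))
  genes <- c(genes, tie)
  names(genes) <- mcols(genes)$geneId
  GenomeInfoDb::seqlengths(genes) <- c(chr1 = L)
  tssDf <- data.frame(
    position = c(950, 940, 4500, 4600, 6500, 10700),
    strand   = c("+", "+", "+", "-", "+", "+"),
    density  = c(100, 40, 80, 60, 50, 70),
    expected = c("P", "S", "I", "A", "N", "P"),
    gene     = c("gA", "gA", NA, NA, NA, "gV"))
  gr <- GRanges("chr1", IRanges(tssDf$position, width = 1L),
                strand = tssDf$strand, density = tssDf$density,
                enrichment = 10, conditions = "H20")
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = L)
  list(genome = genome, genes = genes, tss = TssSet(gr),
       expected = data.frame(position = tssDf$position,
                             category = tssDf$expected,
                             geneId = tssDf$gene,
                             stringsAsFactors = FALSE))
}

#' Score called TSSs against planted truth
#'
#' A called site is a true positive when a planted TSS of the same strand
#' lies within `tolerance` bp (each planted TSS can be matched once).
#'
#' @param called a [TssSet-class].
#' @param truthTss `data.frame` with `position` and `strand` (the `tss`
#'   element of a generator's truth).
#' @param tolerance matching tolerance in bp (default 2).
#' @return list with `recall`, `precision`, `nCalled`, `nTrue`,
#'   `truePositives`.
#' @export
scoreTssRecovery <- function(called, truthTss, tolerance = 2) {
  gr <- tssSites(called)
  usedTruth <- rep(FALSE, nrow(truthTss))
  tp <- 0L
  for (i in seq_along(gr)) {
    cand <- which(!usedTruth &
                  truthTss$strand == as.character(strand(gr))[i] &
                  abs(truthTss$position - start(gr)[i]) <= tolerance)
    if (length(cand)) {
      usedTruth[cand[1L]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(recall = if (nrow(truthTss)) tp / nrow(truthTss) else NA_real_,
       precision = if (length(gr)) tp / length(gr) else NA_real_,
       nCalled = length(gr), nTrue = nrow(truthTss),
       truePositives = tp)
}

#' Write a simulated data set to disk in standard formats
#'
#' Writes FASTA, GFF3, per-library bedGraph pairs, the operon table and a
#' JSON ground-truth file, so the full pipeline can be exercised through
#' the same readers used for real data.
#'
#' @param sim output of [generateGenomeAnnotation()].
#' @param profiles output of [simulateEndProfiles()].
#' @param dir output directory (created if needed).
#' @return Named list of paths (including a `manifest` data.frame of
#'   library files), invisibly.
#' @export
writeSimulatedData <- function(sim, profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  gff <- file.path(dir, "annotation.gff3")
  writeAnnotation(sim$genes, gff)
  op <- file.path(dir, "operons.tsv")
  utils::write.table(sim$operons, op, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- do.call(rbind, lapply(profiles, function(p) {
    prefix <- file.path(dir, libraryId(p))
    paths <- writeBedgraphPair(p, prefix)
    data.frame(libraryId = libraryId(p), condition = libCondition(p),
               replicate = libReplicate(p), treatment = treatment(p),
               plusBedgraph = paths[["plus"]],
               minusBedgraph = paths[["minus"]],
               stringsAsFactors = FALSE)
  }))
  mpath <- file.path(dir, "libraries.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tpath <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, tpath, auto_unbox = TRUE, digits = NA)
  invisible(list(genome = fa, annotation = gff, operons = op,
                 manifest = manifest, manifestPath = mpath,
                 truth = tpath))
}
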