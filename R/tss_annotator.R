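#' Classify TSSs relative to gene annotation
#'
#' Applies the five-category positional scheme. For every gene a candidate
#' window runs from `upstream` bp (default 299) upstream to `downstream` bp
#' (default 100) downstream of the first base of its start codon,
#' strand-aware. Each same-strand TSS inside at least one window is
#' assigned to the gene with the nearest start codon (ties to the
#' lexicographically smaller gene id); per gene, the highest-density
#' assigned TSS is primary (`P`, density ties to the most upstream) and the
#' rest are secondary (`S`). Remaining TSSs overlapping a gene body on the
#' same strand are internal (`I`), on the opposite strand antisense (`A`),
#' and all others intergenic (`N`).
#'
#' @param tss a [TssSet-class] (merged total set).
#' @param genes `GRanges` from [readAnnotation()] (needs `geneId` and
#'   `startCodonPos`).
#' @param upstream,downstream window extent in bp around the start codon.
#' @return The [TssSet-class] with `category` and `geneId` filled in.
#' @export
classifyTss <- function(tss, genes, upstream = 299, downstream = 100) {
  gr <- tssSites(tss)
  n <- length(gr)
  category <- rep(NA_character_, n)
  geneId <- rep(NA_character_, n)
  if (n == 0L) return(tss)
  plusGene <- as.character(strand(genes)) == "+"
  scp <- mcols(genes)$startCodonPos
  winStart <- ifelse(plusGene, scp - upstream, scp - downstream)
  winEnd <- ifelse(plusGene, scp + downstream, scp + upstream)
  windows <- GRanges(seqnames(genes),
                     IRanges(pmax(1L, winStart), winEnd),
                     strand = strand(genes))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, windows))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  # nearest start codon wins; ties to smaller gene id
  if (length(ov)) {
    dist <- abs(start(gr)[qh] - scp[sh])
    ordKey <- order(qh, dist, mcols(genes)$geneId[sh])
    first <- !duplicated(qh[ordKey])
    assignedTss <- qh[ordKey][first]
    assignedGene <- sh[ordKey][first]
    geneId[assignedTss] <- mcols(genes)$geneId[assignedGene]
    # per gene: max density -> P (ties most upstream), others -> S
    for (g in unique(assignedGene)) {
      members <- assignedTss[assignedGene == g]
      d <- mcols(gr)$density[members]
      best <- members[d == max(d)]
      if (length(best) > 1L) {
        best <- if (as.character(strand(genes))[g] == "-")
          best[which.max(start(gr)[best])]
        else best[which.min(start(gr)[best])]
      } else best <- best[1L]
      category[members] <- "S"
      category[best] <- "P"
    }
  }
  un <- which(is.na(category))
  if (length(un)) {
    same <- GenomicRanges::findOverlaps(gr[un], genes)
    category[un[unique(S4Vectors::queryHits(same))]] <- "I"
  }
  un <- which(is.na(category))
  if (length(un)) {
    flip <- gr[un]
    strand(flip) <- ifelse(as.character(strand(flip)) == "+", "-", "+")
    anti <- GenomicRanges::findOverlaps(flip, genes)
    category[un[unique(S4Vectors::queryHits(anti))]] <- "A"
  }
  category[is.na(category)] <- "N"
  mcols(gr)$category <- category
  mcols(gr)$geneId <- geneId
  TssSet(gr)
}

#' Extract 5'-UTRs for primary TSSs
#'
#' For every TSS classified `P`, the 5'-UTR length is the strand-aware
#' distance from the TSS to the first base of the start codon; transcripts
#' with a length below `leaderlessMax` nt (default 10) are leaderless. The
#' leader sequence (TSS up to the base before the start codon) is reported
#' as RNA (reverse-complemented for `-` genes, T mapped to U), together
#' with the genomic start codon 3-mer.
#'
#' @param tss a classified [TssSet-class].
#' @param genes annotation `GRanges` (as in [classifyTss()]).
#' @param genome `DNAStringSet`.
#' @param leaderlessMax leaders shorter than this many nt are leaderless.
#' @return A `data.frame` with columns `geneId`, `tssPosition`, `strand`,
#'   `length`, `leaderStatus`, `sequence`, `startCodon`. Lengths `<= 0`
#'   give an empty sequence.
#' @export
extractUtrs <- function(tss, genes, genome, leaderlessMax = 10) {
  gr <- tssSites(tss)
  prim <- gr[!is.na(mcols(gr)$category) & mcols(gr)$category == "P"]
  if (length(prim) == 0L)
    return(data.frame(geneId = character(), tssPosition = integer(),
                      strand = character(), length = integer(),
                      leaderStatus = character(), sequence = character(),
                      startCodon = character()))
  gidx <- match(mcols(prim)$geneId, mcols(genes)$geneId)
  if (anyNA(gidx)) stop("primary TSS references unknown gene")
  scp <- mcols(genes)$startCodonPos[gidx]
  minus <- as.character(strand(prim)) == "-"
  len <- ifelse(minus, start(prim) - scp, scp - start(prim))
  seqs <- character(length(prim))
  for (i in seq_along(prim)) {
    if (len[i] <= 0L) { seqs[i] <- ""; next }
    chrom <- genome[[as.character(seqnames(prim))[i]]]
    s <- if (minus[i])
      Biostrings::reverseComplement(
        Biostrings::subseq(chrom, scp[i] + 1L, start(prim)[i]))
    else Biostrings::subseq(chrom, start(prim)[i], scp[i] - 1L)
    seqs[i] <- chartr("T", "U", as.character(s))
  }
  codon <- startCodonAt(genes[gidx], genome)
  data.frame(geneId = mcols(prim)$geneId,
             tssPosition = start(prim),
             strand = as.character(strand(prim)),
             length = as.integer(len),
             leaderStatus = ifelse(len < leaderlessMax, "leaderless",
                                   "leader"),
             sequence = seqs,
             startCodon = codon,
             stringsAsFactors = FALSE)
}

#' Genomic start codon of each gene
#'
#' @param genes annotation `GRanges` with `startCodonPos`.
#' @param genome `DNAStringSet`.
#' @return Character vector of strand-aware start-codon 3-mers (reverse
#'   complemented for `-` genes).
#' @export
startCodonAt <- function(genes, genome) {
  vapply(seq_along(genes), function(i) {
    chrom <- genome[[as.character(seqnames(genes))[i]]]
    scp <- mcols(genes)$startCodonPos[i]
    if (as.character(strand(genes))[i] == "-")
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(chrom, scp - 2L, scp)))
    else as.character(Biostrings::subseq(chrom, scp, scp + 2L))
  }, "")
}

#' Start-codon usage by leader class
#'
#' Tabulates start codons (ATG/GTG/TTG, everything else pooled as `other`)
#' split by leader vs leaderless status; counts sum to the number of input
#' records.
#'
#' @param utrs `data.frame` from [extractUtrs()].
#' @return Integer matrix, rows `ATG,GTG,TTG,other`, columns
#'   `leader,leaderless`.
#' @export
startCodonUsage <- function(utrs) {
  codon <- ifelse(utrs$startCodon %in% c("ATG", "GTG", "TTG"),
                  utrs$startCodon, "other")
  tab <- table(factor(codon, levels = c("ATG", "GTG", "TTG", "other")),
               factor(utrs$leaderStatus,
                      levels = c("leader", "leaderless")))
  m <- matrix(as.integer(tab), nrow = 4,
              dimnames = list(c("ATG", "GTG", "TTG", "other"),
                              c("leader", "leaderless")))
  m
}

#' Nucleotide context around TSSs
#'
#' Base frequencies at the -2, -1, +1, +2, +3 positions around each TSS
#' (+1 is the TSS base itself; strand-aware, reverse complemented on `-`).
#' TSSs within 2 bp of a replicon edge are excluded with a warning.
#'
#' @param tss a [TssSet-class].
#' @param genome `DNAStringSet`.
#' @return 4 x 5 numeric matrix of frequencies (rows A,C,G,T; columns
#'   `-2,-1,+1,+2,+3`), each column summing to 1.
#' @export
tssContextProfile <- function(tss, genome) {
  gr <- tssSites(tss)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  p <- start(gr)
  ok <- p - 2L >= 1L & p + 2L <= lens[as.character(seqnames(gr))]
  if (any(!ok))
    warning(sum(!ok), " TSS(s) within 2 bp of a replicon edge excluded")
  gr <- gr[ok]
  cols <- c("-2", "-1", "+1", "+2", "+3")
  counts <- matrix(0L, nrow = 4, ncol = 5,
                   dimnames = list(c("A", "C", "G", "T"), cols))
  for (i in seq_along(gr)) {
    chrom <- genome[[as.character(seqnames(gr))[i]]]
    s <- Biostrings::subseq(chrom, start(gr)[i] - 2L, start(gr)[i] + 2L)
    if (as.character(strand(gr))[i] == "-")
      s <- Biostrings::reverseComplement(s)
    bases <- strsplit(as.character(s), "")[[1L]]
    for (j in 1:5)
      if (bases[j] %in% rownames(counts))
        counts[bases[j], j] <- counts[bases[j], j] + 1L
    }
  freq <- sweep(counts, 2, pmax(1L, colSums(counts)), "/")
  freq
}

#' Assign TSSs to operons
#'
#' An operon receives every primary or secondary TSS of its first
#' (5'-most) gene. Operons with at least one assigned TSS are flagged
#' `TSS-validated`, the rest `coverage-only`.
#'
#' @param tss a classified [TssSet-class].
#' @param operons `data.frame` with columns `operonId`, `geneId`, `order`
#'   (1 = first gene in transcription direction).
#' @param genes annotation `GRanges`; every operon member must be known.
#' @return A list with `assignments` (`data.frame`: `operonId`, `geneId`,
#'   `tssPosition`, `category`) and `status` (`data.frame`: `operonId`,
#'   `status`).
#' @export
assignTssToOperons <- function(tss, operons, genes) {
  unknown <- setdiff(operons$geneId, mcols(genes)$geneId)
  if (length(unknown))
    stop("operon references unknown gene(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  gr <- tssSites(tss)
  ps <- gr[!is.na(mcols(gr)$category) & mcols(gr)$category %in% c("P", "S")]
  firsts <- operons[operons$order == 1L, c("operonId", "geneId")]
  hit <- match(mcols(ps)$geneId, firsts$geneId)
  keep <- !is.na(hit)
  assignments <- data.frame(
    operonId = firsts$operonId[hit[keep]],
    geneId = mcols(ps)$geneId[keep],
    tssPosition = start(ps)[keep],
    category = mcols(ps)$category[keep],
    stringsAsFactors = FALSE)
  status <- data.frame(
    operonId = firsts$operonId,
    status = ifelse(firsts$operonId %in% assignments$operonId,
                    "TSS-validated", "coverage-only"),
    stringsAsFactors = FALSE)
  list(assignments = assignments[order(assignments$operonId), ,
                                 drop = FALSE],
       status = status[order(status$operonId), , drop = FALSE])
}
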