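#' Read a genome FASTA
#'
#' Reads one replicon per FASTA record into a [Biostrings::DNAStringSet].
#' Sequences are uppercased and `U` is mapped to `T`; anything outside
#' `{A,C,G,T,N}` after that normalization is rejected.
#'
#' @param path path to a FASTA file.
#' @return A `DNAStringSet`, one element per replicon, named by record id
#'   (first whitespace-delimited token of the header).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr", "ACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e)
                     stop("FASTA format error in ", path, ": ",
                          conditionMessage(e)))
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record id: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  chars <- toupper(as.character(seqs))
  chars <- chartr("U", "T", chars)
  if (any(!nzchar(chars))) stop("empty sequence in FASTA record")
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    rec <- which(bad)[1L]
    ch <- regmatches(chars[rec], regexpr("[^ACGTN]", chars[rec]))
    stop("non-IUPAC character '", ch, "' in record '", names(seqs)[rec], "'")
  }
  Biostrings::DNAStringSet(chars)
}

#' Read gene features from GFF3
#'
#' Imports a GFF3 annotation and returns the gene features as a `GRanges`
#' with metadata columns `geneId` (from the `ID` or `locus_tag` attribute),
#' `kind`, and the strand-aware `startCodonPos` (1-based genomic position of
#' the first base of the start codon: `start` on `+`, `end` on `-`).
#' Features on unknown replicons or extending past the replicon end are
#' rejected with the offending record index.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @param genome a `DNAStringSet` as returned by [readGenome()]; provides
#'   replicon names and lengths for bounds checking.
#' @param types feature types to keep (default `"CDS"` and `"gene"`).
#' @return A `GRanges` with `seqlengths` set from `genome`.
#' @export
readAnnotation <- function(path, genome, types = c("CDS", "gene")) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  gff <- gff[as.character(gff$type) %in% types]
  ids <- if (is.null(gff$ID)) rep(NA_character_, length(gff))
         else as.character(gff$ID)
  if (!is.null(gff$locus_tag)) {
    lt <- as.character(gff$locus_tag)
    ids[is.na(ids) | !nzchar(ids)] <- lt[is.na(ids) | !nzchar(ids)]
  }
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad))
    stop("GFF3 record ", bad[1L], ": missing ID/locus_tag attribute")
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  repl <- as.character(GenomicRanges::seqnames(gff))
  unk <- which(!repl %in% names(lens))
  if (length(unk))
    stop("GFF3 record ", unk[1L], " ('", ids[unk[1L]],
         "'): unknown replicon '", repl[unk[1L]], "'")
  oob <- which(GenomicRanges::end(gff) > lens[repl] |
               GenomicRanges::start(gff) < 1L)
  if (length(oob))
    stop("GFF3 record ", oob[1L], " ('", ids[oob[1L]],
         "'): coordinates outside replicon bounds")
  if (any(as.character(strand(gff)) == "*"))
    stop("unstranded gene feature in GFF3")
  gr <- GRanges(repl, IRanges(GenomicRanges::start(gff),
                              GenomicRanges::end(gff)),
                strand = strand(gff))
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  GenomeInfoDb::seqlengths(gr) <- lens
  mcols(gr)$geneId <- ids
  mcols(gr)$kind <- as.character(gff$type)
  mcols(gr)$startCodonPos <- ifelse(as.character(strand(gr)) == "+",
                                    GenomicRanges::start(gr),
                                    GenomicRanges::end(gr))
  names(gr) <- ids
  sort(gr, ignore.strand = TRUE)
}

#' Write gene features to GFF3
#'
#' Inverse of [readAnnotation()]; coordinates round-trip exactly.
#'
#' @param genes `GRanges` with `geneId` and `kind` metadata.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(genes, path) {
  out <- genes
  mcols(out) <- NULL
  mcols(out)$type <- if (is.null(genes$kind)) "CDS" else genes$kind
  mcols(out)$ID <- genes$geneId
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a stranded bedGraph pair into an EndProfile
#'
#' One bedGraph per strand; 0-based half-open intervals carrying integer
#' 5'-end counts are expanded to per-position sparse counts (1-based
#' internally). Zero-valued intervals are dropped; negative values and
#' overlapping intervals on one strand are format errors.
#'
#' @param plusPath,minusPath bedGraph files for the `+` and `-` strand.
#' @param libraryId,condition,replicate,treatment library metadata (see
#'   [EndProfile()]).
#' @param seqlengths optional named replicon lengths for bounds checking.
#' @return An [EndProfile-class].
#' @export
readBedgraphPair <- function(plusPath, minusPath, libraryId,
                             condition = "cond", replicate = 1L,
                             treatment = "RPP+", seqlengths = NULL) {
  readOne <- function(path, strd) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (any(gr$score < 0))
      stop("negative count in bedGraph ", path)
    gr <- gr[gr$score != 0]
    if (length(gr) &&
        any(IRanges::countOverlaps(gr, gr, ignore.strand = TRUE) > 1L))
      stop("overlapping intervals in bedGraph ", path)
    if (length(gr) == 0L)
      return(GRanges(score = numeric()))
    pos <- unlist(lapply(seq_along(gr), function(i)
      seq.int(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])))
    rep_i <- rep(seq_along(gr), width(gr))
    GRanges(as.character(seqnames(gr))[rep_i], IRanges(pos, width = 1L),
            strand = strd, score = gr$score[rep_i])
  }
  counts <- suppressWarnings(c(readOne(plusPath, "+"),
                               readOne(minusPath, "-")))
  EndProfile(libraryId, condition, replicate, treatment, counts,
             seqlengths = seqlengths)
}

#' Write an EndProfile to a stranded bedGraph pair
#'
#' Adjacent positions with equal counts are collapsed into intervals
#' (0-based half-open in the files), so [readBedgraphPair()] round-trips the
#' profile exactly.
#'
#' @param profile an [EndProfile-class].
#' @param prefix output path prefix; files are `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph`.
#' @return Named character vector of the two paths, invisibly.
#' @export
writeBedgraphPair <- function(profile, prefix) {
  gr <- endCounts(profile)
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (strd in c("+", "-")) {
    sub <- gr[strand(gr) == strd]
    strand(sub) <- "*"
    p <- paths[[if (strd == "+") "plus" else "minus"]]
    rtracklayer::export(sort(sub), p, format = "bedGraph")
    if (length(sub) == 0L) file.create(p)
  }
  invisible(paths)
}

#' Write classified TSS outputs
#'
#' Writes three files describing a (classified) [TssSet-class]:
#' a TSV (`<prefix>.tss.tsv`) with 1-based positions for reporting, a BED6
#' track (`<prefix>.tss.bed`, 0-based, `name` = category, `score` = density
#' scaled to 0-1000) and a JSON run summary (`<prefix>.tss.summary.json`)
#' with the per-category counts.
#'
#' @param tss a [TssSet-class].
#' @param prefix output path prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
writeTssOutputs <- function(tss, prefix) {
  gr <- tssSites(tss)
  tab <- tssTable(tss)
  tab <- cbind(tssId = if (nrow(tab)) sprintf("TSS%04d", seq_len(nrow(tab)))
               else character(), tab)
  paths <- c(tsv = paste0(prefix, ".tss.tsv"),
             bed = paste0(prefix, ".tss.bed"),
             json = paste0(prefix, ".tss.summary.json"))
  utils::write.table(tab, paths[["tsv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- gr
  mcols(bed) <- NULL
  nm <- mcols(gr)$category
  nm[is.na(nm)] <- "U"
  mcols(bed)$name <- nm
  dmax <- if (length(gr)) max(mcols(gr)$density) else 1
  mcols(bed)$score <- if (length(gr))
    as.integer(round(1000 * mcols(gr)$density / dmax)) else integer()
  rtracklayer::export(bed, paths[["bed"]], format = "BED")
  if (length(bed) == 0L) file.create(paths[["bed"]])
  counts <- as.list(tssCategoryCounts(tss))
  counts$total <- length(tss)
  jsonlite::write_json(counts, paths[["json"]], auto_unbox = TRUE)
  invisible(paths)
}

#' Read a TSS TSV written by writeTssOutputs back into a TssSet
#'
#' @param path the `.tss.tsv` file.
#' @return A [TssSet-class].
#' @export
readTssTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = list(conditions = "character"))
  gr <- GRanges(tab$replicon, IRanges(tab$position, width = 1L),
                strand = tab$strand, density = tab$density,
                enrichment = tab$enrichment,
                conditions = as.character(tab$conditions),
                category = as.character(tab$category),
                geneId = as.character(tab$geneId),
                scope = as.character(tab$scope))
  TssSet(gr)
}
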