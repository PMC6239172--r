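#' Median-of-ratios size factors
#'
#' Computes one positive scaling factor per library from a raw count matrix
#' (genes or genomic bins in rows, libraries in columns): each count is
#' divided by the row geometric mean, and the library's size factor is the
#' median of those ratios over the rows where all libraries have positive
#' counts. Libraries identical to the reference pseudo-sample get factor 1.
#'
#' @param countTable non-negative numeric matrix, rows = genes/bins,
#'   columns = libraries (column names become library ids).
#' @return Named numeric vector of size factors, all `> 0`.
#' @examples
#' computeSizeFactors(cbind(a = c(2, 6), b = c(4, 12)))
#' @export
computeSizeFactors <- function(countTable) {
  countTable <- as.matrix(countTable)
  if (any(countTable < 0)) stop("counts must be non-negative")
  keep <- rowSums(countTable > 0) == ncol(countTable)
  if (!any(keep))
    stop("normalization error: no row with all-positive counts")
  m <- countTable[keep, , drop = FALSE]
  loggeo <- rowMeans(log(m))
  sf <- apply(m, 2L, function(col) exp(stats::median(log(col) - loggeo)))
  if (is.null(names(sf)))
    names(sf) <- colnames(countTable)
  sf
}

#' Apply size-factor normalization to an EndProfile
#'
#' Divides every stored 5'-end count by the library's size factor; sparsity
#' is preserved and the profile is flagged as normalized.
#'
#' @param profile an [EndProfile-class].
#' @param sizeFactors named vector containing `libraryId(profile)`.
#' @return The normalized [EndProfile-class].
#' @export
normalizeProfile <- function(profile, sizeFactors) {
  id <- libraryId(profile)
  if (!id %in% names(sizeFactors))
    stop("no size factor for library '", id, "'")
  s <- sizeFactors[[id]]
  if (!is.finite(s) || s <= 0) stop("size factor must be positive")
  out <- profile
  mcols(out@counts)$score <- mcols(out@counts)$score / s
  out@normalized <- TRUE
  out
}

#' Detect candidate TSS positions
#'
#' Every position whose normalized 5'-end density reaches `minDensity` is a
#' candidate TSS, reported per replicon/strand in position order.
#'
#' @param profile a normalized [EndProfile-class].
#' @param minDensity density floor in normalized units (default 5).
#' @return Width-1 `GRanges` with `density` metadata, sorted by position.
#' @export
detectCandidates <- function(profile, minDensity = 5) {
  gr <- endCounts(profile)
  gr <- gr[mcols(gr)$score >= minDensity]
  out <- GRanges(seqnames(gr), IRanges(start(gr), width = 1L),
                 strand = strand(gr), density = mcols(gr)$score)
  GenomeInfoDb::seqinfo(out) <- GenomeInfoDb::seqinfo(gr)
  sort(out, ignore.strand = TRUE)
}

# Split sorted positions into chains with consecutive gaps <= gap.
.chainBreaks <- function(pos, gap) {
  if (length(pos) <= 1L) return(rep(1L, length(pos)))
  cumsum(c(TRUE, diff(pos) > gap))
}

#' Cluster candidate peaks and pick sub-cluster representatives
#'
#' Reproduces the two-stage peak grouping of the TSS workflow: candidates on
#' one replicon/strand are first clustered by chaining consecutive gaps of
#' at most `clusterGap` bp (default 300); within an initial cluster,
#' adjacent peaks are joined into one sub-cluster when the population
#' standard deviation of the pair, `|a-b|/2`, is below `pairSdMax` (default
#' 15, i.e. gap < 30 bp). The representative of each sub-cluster is its
#' highest-density member; density ties break toward the most upstream
#' position (strand-aware).
#'
#' @param candidates `GRanges` from [detectCandidates()] (any mixture of
#'   replicons/strands; each is processed separately).
#' @param clusterGap initial clustering gap in bp.
#' @param pairSdMax adjacent-pair standard-deviation threshold in bp.
#' @return A list with `representatives` (width-1 `GRanges` with `density`)
#'   and `membership` (integer vector assigning each input candidate, in
#'   input order, to a sub-cluster).
#' @export
clusterCandidates <- function(candidates, clusterGap = 300, pairSdMax = 15) {
  n <- length(candidates)
  membership <- integer(n)
  repIdx <- integer(0)
  if (n) {
    key <- paste(as.character(seqnames(candidates)),
                 as.character(strand(candidates)))
    nextSub <- 0L
    for (k in unique(key)) {
      idx <- which(key == k)
      pos <- start(candidates)[idx]
      if (is.unsorted(pos)) stop("candidates must be sorted by position")
      dens <- mcols(candidates)$density[idx]
      init <- .chainBreaks(pos, clusterGap)
      for (ic in unique(init)) {
        ii <- idx[init == ic]
        p <- start(candidates)[ii]
        # adjacent pair (a,b) joined iff population SD |a-b|/2 < pairSdMax
        sub <- .chainBreaks(p, 2 * pairSdMax - 1e-9)
        for (sc in unique(sub)) {
          nextSub <- nextSub + 1L
          mem <- ii[sub == sc]
          membership[mem] <- nextSub
          d <- mcols(candidates)$density[mem]
          best <- mem[d == max(d)]
          if (length(best) > 1L) {
            up <- if (as.character(strand(candidates))[best[1L]] == "-")
              which.max(start(candidates)[best])
            else which.min(start(candidates)[best])
            best <- best[up]
          } else best <- best[1L]
          repIdx <- c(repIdx, best)
        }
      }
    }
  }
  reps <- candidates[repIdx]
  list(representatives = sort(reps, ignore.strand = TRUE),
       membership = membership)
}

#' RPP+/RPP- enrichment ratio at a position
#'
#' Ratio of pseudocounted normalized densities,
#' `(dPlus + c) / (dMinus + c)`, optionally summing densities over a window
#' of `windowHalfWidth` bp around the position.
#'
#' @param position 1-based position.
#' @param seqname,strd replicon and strand of the position.
#' @param rppPlus,rppMinus normalized [EndProfile-class] objects from the
#'   same condition/replicate.
#' @param pseudocount `c`, in normalized units (default 1).
#' @param windowHalfWidth half-width in bp over which densities are summed
#'   (default 0: the exact position).
#' @return The enrichment ratio (scalar).
#' @export
enrichmentRatio <- function(position, seqname, strd, rppPlus, rppMinus,
                            pseudocount = 1, windowHalfWidth = 0) {
  dens <- function(profile) {
    gr <- endCounts(profile)
    hit <- seqnames(gr) == seqname & strand(gr) == strd &
      abs(start(gr) - position) <= windowHalfWidth
    sum(mcols(gr)$score[as.logical(hit)])
  }
  (dens(rppPlus) + pseudocount) / (dens(rppMinus) + pseudocount)
}

# Vectorized enrichment for a set of representative positions.
.enrichmentAt <- function(reps, rppPlus, rppMinus, pseudocount,
                          windowHalfWidth = 0) {
  if (length(reps) == 0L) return(numeric())
  minus <- endCounts(rppMinus)
  win <- GenomicRanges::resize(reps, 1L + 2L * windowHalfWidth, fix = "center")
  ov <- GenomicRanges::findOverlaps(win, minus)
  dminus <- numeric(length(reps))
  if (length(ov)) {
    agg <- tapply(mcols(minus)$score[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), sum)
    dminus[as.integer(names(agg))] <- agg
  }
  dplus <- mcols(reps)$density
  if (windowHalfWidth > 0) {
    plus <- endCounts(rppPlus)
    ovp <- GenomicRanges::findOverlaps(win, plus)
    dplus <- numeric(length(reps))
    aggp <- tapply(mcols(plus)$score[S4Vectors::subjectHits(ovp)],
                   S4Vectors::queryHits(ovp), sum)
    dplus[as.integer(names(aggp))] <- aggp
  }
  (dplus + pseudocount) / (dminus + pseudocount)
}

#' Default TSS-calling parameters
#'
#' @return A list of the tunable thresholds of the TSS caller: `clusterGap`
#'   (300 bp), `pairSdMax` (15 bp), `enrichmentMin` (2), `mergeWindow`
#'   (4 bp), `minDensity` (5 normalized units), `pseudocount` (1),
#'   `replicateWindow` (4 bp), `windowHalfWidth` (0 bp).
#' @export
tssCallingConfig <- function() {
  list(clusterGap = 300, pairSdMax = 15, enrichmentMin = 2,
       mergeWindow = 4, minDensity = 5, pseudocount = 1,
       replicateWindow = 4, windowHalfWidth = 0)
}

#' Call TSSs for one condition
#'
#' For each biological replicate, the RPP+ profile is normalized, scanned
#' for candidate peaks, clustered ([clusterCandidates()]), and each
#' sub-cluster representative is kept when its RPP+/RPP- enrichment reaches
#' `enrichmentMin` (default twofold). A condition TSS then requires
#' enriched representatives from both replicates within
#' `replicateWindow` bp (default +/-4); the reported position, density and
#' enrichment are those of the higher-density replicate representative.
#' With a single replicate the reproducibility step is skipped with a
#' warning.
#'
#' @param plusProfiles list of RPP+ [EndProfile-class], one per replicate.
#' @param minusProfiles list of matching RPP- profiles (same order).
#' @param sizeFactors named size factors covering all supplied libraries,
#'   computed jointly (see [computeSizeFactors()], [binProfiles()]).
#' @param config parameter list, see [tssCallingConfig()].
#' @return A [TssSet-class] with `conditions` set to the condition label.
#' @export
callConditionTss <- function(plusProfiles, minusProfiles, sizeFactors,
                             config = tssCallingConfig()) {
  if (length(plusProfiles) != length(minusProfiles) ||
      length(plusProfiles) == 0L)
    stop("each RPP+ replicate needs an RPP- partner")
  cond <- libCondition(plusProfiles[[1L]])
  nrep <- length(plusProfiles)
  if (nrep == 1L)
    warning("single replicate for condition '", cond,
            "': reproducibility filter skipped")
  perRep <- lapply(seq_len(nrep), function(r) {
    plus <- normalizeProfile(plusProfiles[[r]], sizeFactors)
    minus <- normalizeProfile(minusProfiles[[r]], sizeFactors)
    cand <- detectCandidates(plus, config$minDensity)
    reps <- clusterCandidates(cand, config$clusterGap,
                              config$pairSdMax)$representatives
    enr <- .enrichmentAt(reps, plus, minus, config$pseudocount,
                         config$windowHalfWidth)
    reps <- reps[enr >= config$enrichmentMin]
    mcols(reps)$enrichment <- enr[enr >= config$enrichmentMin]
    reps
  })
  if (nrep == 1L) {
    kept <- perRep[[1L]]
  } else {
    # pairwise reproducibility across the replicate series: a site must be
    # supported in every replicate within the window; report the overall
    # highest-density supporting representative
    base <- perRep[[1L]]
    keep <- rep(TRUE, length(base))
    best <- base
    for (r in 2L:nrep) {
      other <- perRep[[r]]
      if (length(other) == 0L) { keep[] <- FALSE; break }
      near <- GenomicRanges::findOverlaps(
        GenomicRanges::resize(base, 1L + 2L * config$replicateWindow,
                              fix = "center"), other)
      hit <- rep(FALSE, length(base))
      for (i in seq_along(base)) {
        j <- S4Vectors::subjectHits(near)[S4Vectors::queryHits(near) == i]
        if (length(j)) {
          hit[i] <- TRUE
          jbest <- j[which.max(mcols(other)$density[j])]
          if (mcols(other)$density[jbest] > mcols(best)$density[i])
            best[i] <- other[jbest]
        }
      }
      keep <- keep & hit
    }
    kept <- best[keep]
  }
  if (length(kept)) mcols(kept)$conditions <- cond
  else mcols(kept)$conditions <- character()
  TssSet(kept)
}

#' Merge per-condition TSS sets into a total TSS set
#'
#' Greedy +/-window merging: the unmerged TSS of highest density seeds a
#' total TSS, absorbs every unmerged TSS within `window` bp on the same
#' replicon/strand (their condition labels are unioned), and the process
#' repeats. Each merged TSS is labelled by scope: `constitutive` (seen in
#' all conditions), `conditional` (two or more) or `specific` (one).
#'
#' @param tssSets list of [TssSet-class] (typically one per condition).
#' @param window merge half-window in bp (default 4).
#' @param nConditions total number of conditions defining "constitutive";
#'   defaults to the number of distinct condition labels in the input.
#' @return A [TssSet-class].
#' @export
mergeTssSets <- function(tssSets, window = 4, nConditions = NULL) {
  grs <- lapply(tssSets, tssSites)
  all <- suppressWarnings(do.call(c, unname(grs)))
  condLabels <- unique(unlist(strsplit(
    stats::na.omit(mcols(all)$conditions), ",")))
  if (is.null(nConditions)) nConditions <- max(1L, length(condLabels))
  if (length(all) == 0L) return(TssSet(all))
  pos <- start(all); dens <- mcols(all)$density
  key <- paste(as.character(seqnames(all)), as.character(strand(all)))
  unmerged <- rep(TRUE, length(all))
  ord <- order(-dens, pos)
  outIdx <- integer(0); outConds <- character(0); outEnr <- numeric(0)
  for (i in ord) {
    if (!unmerged[i]) next
    grab <- which(unmerged & key == key[i] & abs(pos - pos[i]) <= window)
    unmerged[grab] <- FALSE
    outIdx <- c(outIdx, i)
    cl <- unique(unlist(strsplit(stats::na.omit(
      mcols(all)$conditions[grab]), ",")))
    outConds <- c(outConds, paste(sort(cl), collapse = ","))
    enr <- mcols(all)$enrichment[grab]
    outEnr <- c(outEnr, if (all(is.na(enr))) NA_real_ else
      max(enr, na.rm = TRUE))
  }
  merged <- all[outIdx]
  mcols(merged)$conditions <- outConds
  mcols(merged)$enrichment <- outEnr
  ncond <- lengths(strsplit(outConds, ","))
  mcols(merged)$scope <- ifelse(
    ncond >= nConditions & nConditions >= 2L, "constitutive",
    ifelse(ncond >= 2L, "conditional", "specific"))
  TssSet(merged)
}

#' Bin 5'-end profiles into a count matrix for size-factor estimation
#'
#' Sums raw 5'-end counts of each library in fixed-width genomic bins
#' (strand-collapsed), yielding the bins x libraries matrix that
#' [computeSizeFactors()] expects when no gene-level count table is
#' available for the dRNA-seq libraries.
#'
#' @param profiles list of [EndProfile-class].
#' @param binSize bin width in bp (default 200).
#' @return Numeric matrix, one column per library (named by library id).
#' @export
binProfiles <- function(profiles, binSize = 200) {
  stopifnot(length(profiles) > 0L)
  allPos <- lapply(profiles, function(p) {
    gr <- endCounts(p)
    data.frame(bin = paste0(as.character(seqnames(gr)), ":",
                            (start(gr) - 1L) %/% binSize),
               score = mcols(gr)$score)
  })
  bins <- sort(unique(unlist(lapply(allPos, function(d) d$bin))))
  mat <- vapply(allPos, function(d) {
    v <- tapply(d$score, factor(d$bin, levels = bins), sum, default = 0)
    as.numeric(v)
  }, numeric(length(bins)))
  mat <- matrix(mat, nrow = length(bins),
                dimnames = list(bins, vapply(profiles, libraryId, "")))
  mat
}
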