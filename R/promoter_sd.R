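#' Extract upstream promoter windows
#'
#' Returns the strand-aware sequence covering offsets `-width .. -1`
#' relative to each TSS (+1 base excluded), reverse complemented for `-`
#' strand sites. TSSs closer than `width` to a replicon edge are skipped
#' with a warning.
#'
#' @param tss a [TssSet-class].
#' @param genome `DNAStringSet`.
#' @param width window width in bp (default 50).
#' @return Named character vector of windows; names are
#'   `replicon:position:strand` identifiers.
#' @export
extractUpstreamWindows <- function(tss, genome, width = 50) {
  stopifnot(width >= 1)
  gr <- tssSites(tss)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  p <- start(gr)
  minus <- as.character(strand(gr)) == "-"
  ok <- ifelse(minus, p + width <= lens[as.character(seqnames(gr))],
               p - width >= 1L)
  if (any(!ok))
    warning(sum(!ok), " TSS(s) closer than ", width,
            " bp to a replicon edge skipped")
  gr <- gr[ok]; p <- p[ok]; minus <- minus[ok]
  out <- vapply(seq_along(gr), function(i) {
    chrom <- genome[[as.character(seqnames(gr))[i]]]
    if (minus[i])
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(chrom, p[i] + 1L, p[i] + width)))
    else as.character(Biostrings::subseq(chrom, p[i] - width, p[i] - 1L))
  }, "")
  names(out) <- paste(as.character(seqnames(gr)), p,
                      as.character(strand(gr)), sep = ":")
  out
}

# mismatches between equal-length strings
.mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# Best consensus match in a window. offsets: allowed start offsets of the
# element's first base (relative coordinate system of the window). The
# window string is indexed so that windowOffset0 is the offset of its first
# character. Ties: fewer mismatches, then 3'-most (largest start offset).
.scanConsensus <- function(window, consensus, startRange, windowOffset0,
                           maxMismatch) {
  k <- nchar(consensus)
  hits <- NULL
  for (s in seq(startRange[1L], startRange[2L])) {
    idx <- s - windowOffset0 + 1L
    if (idx < 1L || idx + k - 1L > nchar(window)) next
    sub <- substr(window, idx, idx + k - 1L)
    mm <- .mismatches(sub, consensus)
    if (mm <= maxMismatch &&
        (is.null(hits) || mm < hits$mismatches ||
         (mm == hits$mismatches && s > hits$offset)))
      hits <- list(offset = s, matched = sub, mismatches = mm)
  }
  hits
}

#' Scan a promoter window for -10 and -35 boxes
#'
#' Mismatch-tolerant consensus scanning anchored on the canonical sigma-70
#' boxes: the -10 hexamer `TATAAT` must lie fully within TSS offsets
#' `[-20, -5]` and the -35 hexamer `TTGACA` within `[-36, -23]`. The best
#' hit per element has the fewest mismatches (at most `maxMismatch`,
#' default 1), ties resolved 3'-most. When both boxes are found the spacer
#' is the gap in bp between the -35 box end and the -10 box start.
#'
#' @param window upstream window string from [extractUpstreamWindows()]
#'   (its last character is offset -1).
#' @param maxMismatch maximum mismatches per element.
#' @param m10Range,m35Range allowed offset ranges (first..last offset the
#'   element may cover).
#' @return A `data.frame` with one row per found element (columns
#'   `element`, `offset` of the element's first base, `matched`,
#'   `mismatches`, `spacer`); zero rows when nothing qualifies.
#' @export
scanPromoterElements <- function(window, maxMismatch = 1,
                                 m10Range = c(-20, -5),
                                 m35Range = c(-36, -23)) {
  if (nchar(window) < 6) stop("window shorter than element")
  off0 <- -nchar(window)
  m10 <- .scanConsensus(window, "TATAAT",
                        c(m10Range[1L], m10Range[2L] - 5L), off0,
                        maxMismatch)
  m35 <- .scanConsensus(window, "TTGACA",
                        c(m35Range[1L], m35Range[2L] - 5L), off0,
                        maxMismatch)
  spacer <- if (!is.null(m10) && !is.null(m35))
    m10$offset - (m35$offset + 5L) - 1L else NA_integer_
  rows <- list()
  if (!is.null(m35))
    rows <- c(rows, list(data.frame(element = "minus35",
                                    offset = m35$offset,
                                    matched = m35$matched,
                                    mismatches = m35$mismatches,
                                    spacer = spacer)))
  if (!is.null(m10))
    rows <- c(rows, list(data.frame(element = "minus10",
                                    offset = m10$offset,
                                    matched = m10$matched,
                                    mismatches = m10$mismatches,
                                    spacer = spacer)))
  if (length(rows)) do.call(rbind, rows)
  else data.frame(element = character(), offset = integer(),
                  matched = character(), mismatches = integer(),
                  spacer = integer())
}

#' Scan a 5'-UTR for a Shine-Dalgarno motif
#'
#' Looks for the best match to the AG-rich consensus `AGGAGG` whose six
#' bases lie fully within offsets `[-20, -5]` relative to the start codon,
#' requiring at least `minIdentity` identities (default 4 of 6). Ties go to
#' the match nearest the start codon.
#'
#' @param utr one row of the [extractUtrs()] table (needs `sequence`,
#'   `length`, `leaderStatus`).
#' @param minIdentity minimum identities to the consensus.
#' @param sdRange allowed offset range relative to the start codon.
#' @return A one-row `data.frame` (`offset`, `matched`, `identities`) or
#'   `NULL` when no position qualifies.
#' @export
scanSdMotif <- function(utr, minIdentity = 4, sdRange = c(-20, -5)) {
  if (utr$leaderStatus != "leader" || utr$length < 5) return(NULL)
  seqDna <- chartr("U", "T", utr$sequence)
  L <- nchar(seqDna)
  best <- NULL
  for (s in seq(sdRange[1L], sdRange[2L] - 5L)) {
    idx <- L + s + 1L          # offset -L is the first UTR base
    if (idx < 1L || idx + 5L > L) next
    sub <- substr(seqDna, idx, idx + 5L)
    ident <- 6L - .mismatches(sub, "AGGAGG")
    if (ident >= minIdentity &&
        (is.null(best) || ident > best$identities ||
         (ident == best$identities && s > best$offset)))
      best <- list(offset = s, matched = sub, identities = ident)
  }
  if (is.null(best)) return(NULL)
  data.frame(offset = best$offset, matched = best$matched,
             identities = best$identities)
}

#' Promoter and SD scan over a whole TSS set
#'
#' Convenience wrapper running [extractUpstreamWindows()] +
#' [scanPromoterElements()] over all TSSs and [scanSdMotif()] over all
#' leader UTRs.
#'
#' @param tss a [TssSet-class].
#' @param genome `DNAStringSet`.
#' @param utrs optional [extractUtrs()] table for the SD scan.
#' @param width upstream window width.
#' @param maxMismatch maximum promoter-box mismatches.
#' @return A `data.frame` with columns `tssId`, `element`, `offset`,
#'   `matched`, `mismatches`, `spacer` (promoter rows) plus SD rows
#'   (`element = "SD"`, offset relative to the start codon, `mismatches` =
#'   6 - identities, `tssId` = gene id).
#' @export
scanAllPromoters <- function(tss, genome, utrs = NULL, width = 50,
                             maxMismatch = 1) {
  wins <- extractUpstreamWindows(tss, genome, width)
  out <- list()
  for (i in seq_along(wins)) {
    hits <- scanPromoterElements(wins[[i]], maxMismatch)
    if (nrow(hits))
      out <- c(out, list(cbind(tssId = names(wins)[i], hits)))
  }
  if (!is.null(utrs) && nrow(utrs)) {
    for (i in seq_len(nrow(utrs))) {
      sd <- scanSdMotif(utrs[i, ])
      if (!is.null(sd))
        out <- c(out, list(data.frame(
          tssId = utrs$geneId[i], element = "SD", offset = sd$offset,
          matched = sd$matched, mismatches = 6L - sd$identities,
          spacer = NA_integer_)))
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(tssId = character(), element = character(),
                  offset = integer(), matched = character(),
                  mismatches = integer(), spacer = integer())
}
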