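#' Accessors for EndProfile and TssSet
#'
#' `libraryId()`, `libCondition()`, `libReplicate()`, `treatment()` return
#' the library metadata of an [EndProfile-class]; `endCounts()` returns its
#' sparse count `GRanges`; `isNormalized()` reports whether size-factor
#' scaling has been applied. `tssSites()` returns the underlying `GRanges`
#' of a [TssSet-class] and `tssTable()` a plain `data.frame` view (1-based
#' positions). `tssCategoryCounts()` tabulates the five categories.
#'
#' @param x an `EndProfile` or `TssSet`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @rdname accessors
#' @export
setGeneric("libCondition", function(x) standardGeneric("libCondition"))
#' @rdname accessors
#' @export
setGeneric("libReplicate", function(x) standardGeneric("libReplicate"))
#' @rdname accessors
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))
#' @rdname accessors
#' @export
setGeneric("endCounts", function(x) standardGeneric("endCounts"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("tssSites", function(x) standardGeneric("tssSites"))

#' @rdname accessors
#' @export
setMethod("libraryId", "EndProfile", function(x) x@libraryId)
#' @rdname accessors
#' @export
setMethod("libCondition", "EndProfile", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("libReplicate", "EndProfile", function(x) x@replicate)
#' @rdname accessors
#' @export
setMethod("treatment", "EndProfile", function(x) x@treatment)
#' @rdname accessors
#' @export
setMethod("endCounts", "EndProfile", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("isNormalized", "EndProfile", function(x) x@normalized)
#' @rdname accessors
#' @export
setMethod("tssSites", "TssSet", function(x) x@sites)

#' @rdname accessors
#' @export
tssTable <- function(x) {
  gr <- tssSites(x)
  data.frame(
    replicon = as.character(GenomicRanges::seqnames(gr)),
    position = GenomicRanges::start(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    S4Vectors::mcols(gr),
    stringsAsFactors = FALSE
  )
}

#' @rdname accessors
#' @export
tssCategoryCounts <- function(x) {
  cats <- S4Vectors::mcols(tssSites(x))$category
  out <- table(factor(cats, levels = c("P", "S", "I", "A", "N")))
  structure(as.integer(c(out, sum(is.na(cats)))),
            names = c(names(out), "unassigned"))
}
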