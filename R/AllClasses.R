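#' EndProfile: stranded 5'-end counts for one dRNA-seq library
#'
#' Holds the sparse per-position counts of aligned-read 5' ends for a single
#' library, together with its metadata (condition, biological replicate and
#' 5'-pyrophosphatase treatment). Positions are stored as width-1
#' [GenomicRanges::GRanges] with a `score` column holding the raw (or, after
#' [normalizeProfile()], scaled) count; zero-count positions are never stored.
#'
#' @slot libraryId single character, unique library identifier.
#' @slot condition single character condition label (e.g. `"H20"`).
#' @slot replicate integer biological replicate index (>= 1).
#' @slot treatment `"RPP+"` (5'-pyrophosphatase treated, primary 5' ends
#'   enriched) or `"RPP-"` (untreated, processed 5' ends).
#' @slot counts width-1 `GRanges` on strands `+`/`-` with numeric `score > 0`.
#' @slot normalized logical; `TRUE` after size-factor scaling.
#'
#' @seealso [EndProfile()], [normalizeProfile()], [detectCandidates()]
#' @export
setClass("EndProfile",
  representation(
    libraryId = "character",
    condition = "character",
    replicate = "integer",
    treatment = "character",
    counts = "GRanges",
    normalized = "logical"
  )
)

setValidity("EndProfile", function(object) {
  msg <- character()
  if (length(object@libraryId) != 1L || !nzchar(object@libraryId))
    msg <- c(msg, "libraryId must be a single non-empty string")
  if (length(object@treatment) != 1L ||
      !object@treatment %in% c("RPP+", "RPP-"))
    msg <- c(msg, "treatment must be 'RPP+' or 'RPP-'")
  if (length(object@replicate) != 1L || is.na(object@replicate) ||
      object@replicate < 1L)
    msg <- c(msg, "replicate must be a positive integer")
  gr <- object@counts
  if (length(gr)) {
    if (any(width(gr) != 1L))
      msg <- c(msg, "counts must be width-1 positions")
    sc <- mcols(gr)$score
    if (is.null(sc) || any(is.na(sc)) || any(sc <= 0))
      msg <- c(msg, "all stored counts must be > 0 (sparse representation)")
    if (any(strand(gr) == "*"))
      msg <- c(msg, "counts must be stranded (+/-)")
    sl <- GenomeInfoDb::seqlengths(gr)
    known <- !is.na(sl[as.character(seqnames(gr))])
    if (any(known)) {
      lim <- sl[as.character(seqnames(gr))][known]
      if (any(start(gr)[known] < 1L) || any(start(gr)[known] > lim))
        msg <- c(msg, "positions must lie within replicon bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EndProfile
#'
#' @param libraryId unique library identifier.
#' @param condition condition label.
#' @param replicate biological replicate index (coerced to integer).
#' @param treatment `"RPP+"` or `"RPP-"`.
#' @param counts width-1 stranded `GRanges` with `score` counts, or a
#'   data.frame with columns `seqnames`, `position` (1-based), `strand`,
#'   `score`.
#' @param seqlengths optional named vector of replicon lengths used for
#'   bounds checking.
#' @return An [EndProfile-class] object. Zero-score entries are dropped.
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(101, 101),
#'   strand = "+", score = 7)
#' EndProfile("lib1", "H20", 1, "RPP+", gr)
#' @export
EndProfile <- function(libraryId, condition, replicate, treatment, counts,
                       seqlengths = NULL) {
  if (is.data.frame(counts)) {
    counts <- GRanges(counts$seqnames,
                      IRanges(counts$position, width = 1L),
                      strand = counts$strand, score = counts$score)
  }
  counts <- counts[mcols(counts)$score != 0]
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(counts) <- seqlengths[
      GenomeInfoDb::seqlevels(counts)]
  counts <- sort(counts, ignore.strand = TRUE)
  new("EndProfile", libraryId = as.character(libraryId),
      condition = as.character(condition),
      replicate = as.integer(replicate),
      treatment = as.character(treatment),
      counts = counts, normalized = FALSE)
}

#' TssSet: a set of (candidate or classified) transcription start sites
#'
#' Wraps a width-1 `GRanges` whose metadata columns carry, per TSS: the
#' normalized peak `density`, the RPP+/RPP- `enrichment` ratio, the
#' supporting `conditions` (comma-separated labels), the positional
#' `category` (`P` primary, `S` secondary, `I` internal, `A` antisense,
#' `N` intergenic, or `NA` before classification), the associated `geneId`
#' and the cross-condition `scope` (`constitutive`/`conditional`/`specific`).
#'
#' @slot sites width-1 `GRanges` with the metadata columns above.
#' @seealso [TssSet()], [mergeTssSets()], [classifyTss()]
#' @export
setClass("TssSet", representation(sites = "GRanges"))

setValidity("TssSet", function(object) {
  gr <- object@sites
  msg <- character()
  need <- c("density", "enrichment", "conditions", "category", "geneId",
            "scope")
  missing <- setdiff(need, colnames(mcols(gr)))
  if (length(missing))
    msg <- c(msg, paste("missing metadata columns:",
                        paste(missing, collapse = ", ")))
  if (length(gr)) {
    if (any(width(gr) != 1L)) msg <- c(msg, "sites must be width-1")
    if (any(strand(gr) == "*")) msg <- c(msg, "sites must be stranded")
    if (!length(missing)) {
      if (any(is.na(mcols(gr)$density)) || any(mcols(gr)$density <= 0))
        msg <- c(msg, "density must be > 0")
      if (any(!is.na(mcols(gr)$conditions) &
              !nzchar(mcols(gr)$conditions)))
        msg <- c(msg, "conditions must be non-empty")
      cat_ok <- is.na(mcols(gr)$category) |
        mcols(gr)$category %in% c("P", "S", "I", "A", "N")
      if (!all(cat_ok))
        msg <- c(msg, "category must be one of P,S,I,A,N or NA")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TssSet
#'
#' @param sites a width-1 stranded `GRanges`; missing metadata columns are
#'   added with `NA` defaults (`density` defaults to the `score` column when
#'   present).
#' @return A [TssSet-class].
#' @export
TssSet <- function(sites = GRanges()) {
  n <- length(sites)
  mc <- mcols(sites)
  fill <- function(v, default) if (is.null(v)) rep(default, n)
                               else rep(v, length.out = n)
  dens <- if (!is.null(mc$density)) mc$density
          else if (!is.null(mc$score)) mc$score else rep(NA_real_, n)
  mcols(sites) <- DataFrame(
    density = dens,
    enrichment = fill(mc$enrichment, NA_real_),
    conditions = fill(mc$conditions, NA_character_),
    category = fill(mc$category, NA_character_),
    geneId = fill(mc$geneId, NA_character_),
    scope = fill(mc$scope, NA_character_))
  new("TssSet", sites = sort(sites, ignore.strand = TRUE))
}

#' @describeIn TssSet-class number of TSSs
#' @param x a `TssSet`
#' @export
setMethod("length", "TssSet", function(x) length(x@sites))

setMethod("show", "EndProfile", function(object) {
  cat("EndProfile '", object@libraryId, "' (", object@condition,
      " rep ", object@replicate, ", ", object@treatment, ")\n", sep = "")
  cat("  ", length(object@counts), " nonzero positions, total ",
      format(sum(mcols(object@counts)$score), digits = 8),
      if (object@normalized) " (normalized)" else " (raw)", "\n", sep = "")
})

setMethod("show", "TssSet", function(object) {
  cat("TssSet with", length(object), "sites\n")
  tab <- tssCategoryCounts(object)
  cat("  categories:", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n")
})
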