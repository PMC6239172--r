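#' Simplified negative-binomial Wald test for differential expression
#'
#' Transparent per-gene test used in place of a full shrinkage-based DE
#' engine: counts are scaled by size factors, the log2 fold change is
#' `log2((meanA + 1) / (meanB + 1))` of group mean normalized counts, and
#' the Wald statistic divides that difference by its delta-method standard
#' error under a per-gene NB variance `mu + alpha * mu^2`, with the
#' dispersion `alpha` estimated by method of moments (pooled over the two
#' groups) and floored at 0 (Poisson). With the small replicate numbers
#' typical of these designs the plug-in variance is noisy, so p-values use
#' a t reference with `nA + nB - 2` degrees of freedom. Genes with all-zero
#' counts are excluded (`NA` results).
#'
#' @param counts integer matrix genes x libraries, or a
#'   `SummarizedExperiment` with a `counts` assay.
#' @param groupA,groupB column names (or indices) of the two groups; at
#'   least 2 libraries each.
#' @param sizeFactors optional named size factors; computed with
#'   [computeSizeFactors()] from the full matrix when missing.
#' @return `data.frame` with columns `geneId`, `baseMean`, `log2FC`, `p`.
#' @export
testDifferentialExpression <- function(counts, groupA, groupB,
                                       sizeFactors = NULL) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 libraries")
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  sf <- sizeFactors[colnames(counts)]
  norm <- sweep(counts, 2L, sf, "/")
  A <- norm[, groupA, drop = FALSE]
  B <- norm[, groupB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  muA <- rowMeans(A); muB <- rowMeans(B)
  allZero <- rowSums(counts) == 0
  log2FC <- log2((muA + 1) / (muB + 1))
  varA <- apply(A, 1L, stats::var)
  varB <- apply(B, 1L, stats::var)
  # method-of-moments dispersion pooled over groups, floored at 0
  momA <- (varA - muA) / muA^2
  momB <- (varB - muB) / muB^2
  alpha <- pmax(0, rowMeans(cbind(momA, momB), na.rm = TRUE))
  alpha[!is.finite(alpha)] <- 0
  vA <- (muA + alpha * muA^2) / nA
  vB <- (muB + alpha * muB^2) / nB
  # delta method onto the log2(mu + 1) scale
  seLog2 <- sqrt(vA / (muA + 1)^2 + vB / (muB + 1)^2) / log(2)
  wald <- log2FC / seLog2
  p <- 2 * stats::pt(-abs(wald), df = nA + nB - 2L)
  p[seLog2 == 0 & log2FC == 0] <- 1
  log2FC[allZero] <- NA_real_
  p[allZero] <- NA_real_
  data.frame(geneId = if (is.null(rownames(counts)))
    as.character(seq_len(nrow(counts))) else rownames(counts),
    baseMean = rowMeans(cbind(A, B)),
    log2FC = log2FC, p = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, `padj_(i) = min_{j >= i} (m/j) p_(j)` capped
#' at 1.
#'
#' @param pvalues numeric vector in `[0, 1]` (`NA` allowed, propagated).
#' @return Adjusted p-values in input order.
#' @export
adjustFdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes across contrasts
#'
#' A gene is selected when `padj < fdrMax` and `|log2FC| > fcMin` in at
#' least `minContrasts` of the supplied contrasts (set `minContrasts = 2`
#' for the "responsive under two or more conditions" reading).
#'
#' @param results named list of `data.frame`s (one per contrast) with
#'   columns `geneId`, `log2FC`, `padj`.
#' @param fcMin minimum absolute log2 fold change (exclusive).
#' @param fdrMax maximum adjusted p (exclusive).
#' @param minContrasts minimum number of qualifying contrasts.
#' @return Character vector of selected gene ids.
#' @export
selectDeg <- function(results, fcMin = 1, fdrMax = 0.01,
                      minContrasts = 1L) {
  if (!length(results)) stop("at least one contrast required")
  hits <- lapply(results, function(r)
    r$geneId[!is.na(r$padj) & r$padj < fdrMax & abs(r$log2FC) > fcMin])
  tab <- table(unlist(hits))
  sort(names(tab)[tab >= minContrasts])
}

#' K-means grouping of expression patterns with an SSE curve
#'
#' Best-of-restarts Lloyd K-means over a complete genes x contrasts
#' log2-fold-change matrix for every `k` in `kRange`; the error sum of
#' squares (SSE, total within-cluster sum of squared distances) is
#' reported per `k`, and labels are returned at `k = kSelect` or, when
#' `NULL`, at the knee of the SSE curve (largest perpendicular distance to
#' the line joining its endpoints).
#'
#' @param mat numeric matrix, genes in rows, no missing values.
#' @param kRange integer vector of cluster numbers to profile.
#' @param restarts random restarts per `k` (default 10).
#' @param seed RNG seed.
#' @param kSelect cluster number at which to report labels, or `NULL`.
#' @return list with `k`, `labels` (named by gene), `sse`
#'   (`data.frame(k, sse)`) and `centers`.
#' @export
kmeansCluster <- function(mat, kRange = 2:10, restarts = 10L, seed = 1L,
                          kSelect = NULL) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must be complete")
  kRange <- sort(unique(as.integer(kRange)))
  if (max(kRange) > nrow(mat)) stop("k exceeds the number of genes")
  fits <- list()
  sse <- numeric(length(kRange))
  set.seed(seed)
  for (idx in seq_along(kRange)) {
    k <- kRange[idx]
    fit <- stats::kmeans(mat, centers = k, nstart = restarts,
                         iter.max = 100L, algorithm = "Lloyd")
    fits[[idx]] <- fit
    sse[idx] <- fit$tot.withinss
  }
  if (is.null(kSelect)) {
    if (length(kRange) >= 3L) {
      x <- kRange; y <- sse
      dx <- x[length(x)] - x[1L]; dy <- y[length(y)] - y[1L]
      dist <- abs(dy * x - dx * y + dx * y[1L] - dy * x[1L]) /
        sqrt(dx^2 + dy^2)
      kSelect <- kRange[which.max(dist)]
    } else kSelect <- kRange[1L]
  }
  sel <- match(kSelect, kRange)
  if (is.na(sel)) stop("kSelect must be in kRange")
  labels <- fits[[sel]]$cluster
  names(labels) <- rownames(mat)
  list(k = kSelect, labels = labels,
       sse = data.frame(k = kRange, sse = sse),
       centers = fits[[sel]]$centers)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' The U statistic counts pairs with `x > y` (half-weight for ties). For
#' tie-free samples with `n + m <= exactMax` (default 16) the p-value is
#' exact, by enumeration of all equally likely rank assignments;
#' otherwise a normal approximation with tie and continuity correction is
#' used.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternative that `x` tends smaller/larger than `y`).
#' @param exactMax size limit for the exact branch.
#' @return list with `U`, `p` and `method`.
#' @export
rankSumTest <- function(x, y, alternative = c("two.sided", "less",
                                              "greater"),
                        exactMax = 16L) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty group")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n + m <= exactMax) {
    ranks <- seq_len(n + m)
    combos <- utils::combn(n + m, n)
    us <- colSums(matrix(ranks[combos], nrow = n)) - n * (n + 1) / 2
    p <- switch(alternative,
                two.sided = mean(abs(us - n * m / 2) >=
                                 abs(U - n * m / 2) - 1e-9),
                less = mean(us <= U + 1e-9),
                greater = mean(us >= U - 1e-9))
    method <- "exact enumeration"
  } else {
    N <- n + m
    tie.tab <- table(r)
    tieCorr <- sum(tie.tab^3 - tie.tab) / (N * (N - 1))
    sigma <- sqrt(n * m / 12 * (N + 1 - tieCorr))
    mu <- n * m / 2
    z <- switch(alternative,
                two.sided = (U - mu - sign(U - mu) * 0.5) / sigma,
                less = (U - mu + 0.5) / sigma,
                greater = (U - mu - 0.5) / sigma)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

#' Median and quartiles per group
#'
#' @param valuesByGroup named list of non-empty numeric vectors.
#' @return `data.frame` with `group`, `median`, `q1`, `q3`, `n`
#'   (quartiles by linear interpolation).
#' @export
summarizeGroupMetric <- function(valuesByGroup) {
  if (any(!lengths(valuesByGroup))) stop("empty group")
  rows <- lapply(names(valuesByGroup), function(g) {
    v <- valuesByGroup[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, median = q[2L], q1 = q[1L], q3 = q[3L],
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Attenuator read-through ratio
#'
#' Ratio of the mean per-base coverage over the gene body to that over its
#' 5' leader; values near 1 indicate read-through, values much below 1
#' premature termination in the leader.
#'
#' @param coverage numeric per-base coverage vector (1-based positions).
#' @param leaderInterval,geneInterval integer `c(start, end)` (1-based,
#'   inclusive) into `coverage`.
#' @return list with `ratio` (`NA` when undefined) and `defined`.
#' @export
readThroughRatio <- function(coverage, leaderInterval, geneInterval) {
  slice <- function(iv) coverage[iv[1L]:iv[2L]]
  leaderMean <- mean(slice(leaderInterval))
  geneMean <- mean(slice(geneInterval))
  if (!is.finite(leaderMean) || leaderMean <= 0) {
    warning("zero leader coverage: read-through ratio undefined")
    return(list(ratio = NA_real_, defined = FALSE))
  }
  list(ratio = geneMean / leaderMean, defined = TRUE)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIj <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  expect <- sumI * sumJ / comb2(length(a))
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expect) return(1)
  (sumIj - expect) / (maxIdx - expect)
}
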