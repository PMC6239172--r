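#' Simplified RNA folding energy parameters
#'
#' The builtin folding engine scores a nested secondary structure as the
#' sum of its base-pair energies: GC/CG pairs -3.0, AU/UA -2.0 and GU/UG
#' wobble pairs -1.0 kcal/mol, with a minimum hairpin loop of `minLoop`
#' unpaired bases. This is a deliberately simple pair-energy model (no
#' stacking, dangles or loop penalties): absolute free energies are not
#' comparable to Turner-model folders, but the ordering it induces
#' (structured much more negative than unstructured) is, and every result
#' can be verified against an exhaustive oracle.
#'
#' @param gc,au,gu pair energies in kcal/mol (all `< 0`).
#' @param minLoop minimum number of unpaired bases in a hairpin loop.
#' @param temperature free-text label recorded as metadata only.
#' @return Parameter list for [foldMfe()] and friends.
#' @export
foldingParams <- function(gc = -3, au = -2, gu = -1, minLoop = 3L,
                          temperature = "37C") {
  stopifnot(gc < 0, au < 0, gu < 0, minLoop >= 0)
  list(gc = gc, au = au, gu = gu, minLoop = as.integer(minLoop),
       temperature = temperature)
}

# energy of pairing bases a,b (characters, RNA), NA if not pairable
.pairEnergy <- function(a, b, params) {
  key <- paste0(a, b)
  switch(key,
         GC = , CG = params$gc,
         AU = , UA = params$au,
         GU = , UG = params$gu,
         NA_real_)
}

.rnaChars <- function(sequence) {
  s <- chartr("Tt", "Uu", toupper(sequence))
  ch <- strsplit(s, "")[[1L]]
  if (length(ch) < 1L) stop("empty sequence")
  if (any(!ch %in% c("A", "C", "G", "U")))
    stop("invalid character in RNA sequence: ",
         ch[which(!ch %in% c("A", "C", "G", "U"))[1L]])
  ch
}

#' Minimum free energy fold under the simplified pair-energy model
#'
#' Dynamic program over all nested (pseudoknot-free) pairings minimizing
#' the sum of pair energies, subject to the minimum hairpin-loop
#' constraint. When no pairing improves on the open chain the result is
#' 0.0 with an all-dot structure. The traceback is deterministic: whenever
#' pairing the 5'-most base attains the optimum it is paired, with the
#' smallest admissible partner.
#'
#' @param sequence RNA string (`A,C,G,U`; `T` is mapped to `U`).
#' @param params from [foldingParams()].
#' @return A list: `sequence` (normalized RNA), `mfe` (kcal/mol, `<= 0`)
#'   and `structure` (dot-bracket, same length).
#' @examples
#' foldMfe("GGGAAACCC")  # -9, (((...)))
#' @export
foldMfe <- function(sequence, params = foldingParams()) {
  ch <- .rnaChars(sequence)
  n <- length(ch)
  ml <- params$minLoop
  W <- matrix(0, n, n)
  emat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
    emat[i, j] <- .pairEnergy(ch[i], ch[j], params)
  if (n >= ml + 2L) {
    for (L in (ml + 2L):n) {
      for (i in 1:(n - L + 1L)) {
        j <- i + L - 1L
        best <- W[i + 1L, j]
        ks <- (i + ml + 1L):j
        for (k in ks) {
          e <- emat[i, k]
          if (is.na(e)) next
          inner <- if (k - 1L > i + 1L || k - 1L == i + 1L)
            W[i + 1L, k - 1L] else 0
          if (k - 1L < i + 1L) inner <- 0
          outer <- if (k + 1L <= j) W[k + 1L, j] else 0
          v <- e + inner + outer
          if (v < best) best <- v
        }
        W[i, j] <- best
      }
    }
  }
  # deterministic traceback: prefer pairing i, smallest partner k
  struct <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (i >= j || j - i < ml + 1L) next
    target <- W[i, j]
    paired <- FALSE
    for (k in (i + ml + 1L):j) {
      e <- emat[i, k]
      if (is.na(e)) next
      inner <- if (k - 1L >= i + 1L) W[i + 1L, k - 1L] else 0
      outer <- if (k + 1L <= j) W[k + 1L, j] else 0
      if (isTRUE(all.equal(e + inner + outer, target)) &&
          e + inner + outer <= target + 1e-12) {
        struct[i] <- "("; struct[k] <- ")"
        if (k - 1L > i) stack <- c(stack, list(c(i + 1L, k - 1L)))
        if (k + 1L < j) stack <- c(stack, list(c(k + 1L, j)))
        paired <- TRUE
        break
      }
    }
    if (!paired) stack <- c(stack, list(c(i + 1L, j)))
  }
  list(sequence = paste(ch, collapse = ""),
       mfe = W[1L, n], structure = paste(struct, collapse = ""))
}

#' Score a dot-bracket structure under the simplified model
#'
#' Validates that the structure is balanced and nested, that every pair is
#' Watson-Crick or GU, and that every pair encloses at least the minimum
#' loop; returns the summed pair energy.
#'
#' @param sequence RNA string.
#' @param structure dot-bracket string of the same length.
#' @param params from [foldingParams()].
#' @return Total energy in kcal/mol.
#' @export
scoreStructure <- function(sequence, structure, params = foldingParams()) {
  ch <- .rnaChars(sequence)
  sc <- strsplit(structure, "")[[1L]]
  if (length(sc) != length(ch))
    stop("structure length differs from sequence length")
  stack <- integer()
  e <- 0
  for (i in seq_along(sc)) {
    if (sc[i] == "(") stack <- c(stack, i)
    else if (sc[i] == ")") {
      if (!length(stack)) stop("unbalanced structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pe <- .pairEnergy(ch[j], ch[i], params)
      if (is.na(pe)) stop("illegal pair ", ch[j], "-", ch[i])
      if (i - j - 1L < params$minLoop)
        stop("pair violates minimum loop")
      e <- e + pe
    } else if (sc[i] != ".") stop("invalid structure character")
  }
  if (length(stack)) stop("unbalanced structure")
  e
}

#' Exhaustive folding oracle
#'
#' Enumerates every legal nested pairing of a short sequence (length at
#' most `maxLen`) and returns the minimum total energy together with the
#' first optimal structure in enumeration order. Same contract as
#' [foldMfe()]; used to verify the dynamic program.
#'
#' @param sequence RNA string, length `<= maxLen`.
#' @param params from [foldingParams()].
#' @param maxLen guard on the enumeration length (default 18).
#' @return As [foldMfe()].
#' @export
bruteForceFold <- function(sequence, params = foldingParams(),
                           maxLen = 18L) {
  ch <- .rnaChars(sequence)
  n <- length(ch)
  if (n > maxLen) stop("sequence longer than enumeration guard (", maxLen,
                       ")")
  ml <- params$minLoop
  enum <- function(i, j) {
    # list of (energy, structure) for region i..j, exhaustively
    if (i > j) return(list(list(e = 0, s = "")))
    out <- list()
    for (sub in enum(i + 1L, j))
      out[[length(out) + 1L]] <- list(e = sub$e,
                                      s = paste0(".", sub$s))
    if (j - i > ml) {
      for (k in (i + ml + 1L):j) {
        pe <- .pairEnergy(ch[i], ch[k], params)
        if (is.na(pe)) next
        for (inner in enum(i + 1L, k - 1L))
          for (outer in enum(k + 1L, j))
            out[[length(out) + 1L]] <-
              list(e = pe + inner$e + outer$e,
                   s = paste0("(", inner$s, ")", outer$s))
      }
    }
    out
  }
  all <- enum(1L, n)
  es <- vapply(all, `[[`, 0, "e")
  best <- which.min(es)
  list(sequence = paste(ch, collapse = ""), mfe = es[best],
       structure = all[[best]]$s)
}

#' Fold a table of 5'-UTRs
#'
#' Runs the selected folding engine over every leader UTR; leaderless
#' entries are reported with `NA` energy and excluded from summaries.
#' Engine failures are recorded per record (`note` column) and do not stop
#' the run.
#'
#' @param utrs `data.frame` from [extractUtrs()].
#' @param params from [foldingParams()].
#' @param engine a function `(sequence, params) -> list(mfe, structure)`;
#'   defaults to the builtin [foldMfe()]. Any external thermodynamic
#'   folder can be plugged in with a thin wrapper.
#' @return `data.frame` with columns `geneId`, `length`, `mfe`,
#'   `structure`, `note`.
#' @export
utrMfeTable <- function(utrs, params = foldingParams(), engine = foldMfe) {
  n <- nrow(utrs)
  out <- data.frame(geneId = utrs$geneId,
                    length = utrs$length,
                    mfe = rep(NA_real_, n),
                    structure = rep(NA_character_, n),
                    note = rep("", n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (utrs$leaderStatus[i] != "leader" || !nzchar(utrs$sequence[i])) {
      out$note[i] <- "leaderless: excluded from folding"
      next
    }
    res <- tryCatch(engine(utrs$sequence[i], params),
                    error = function(e) e)
    if (inherits(res, "error")) {
      out$note[i] <- paste("engine failure:", conditionMessage(res))
    } else {
      out$mfe[i] <- res$mfe
      out$structure[i] <- res$structure
    }
  }
  out
}
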