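# Hairpin-only minimum-free-energy folding.  The model space is a
# single stem-loop: nested pairs with at most 3 unpaired nt per side
# between consecutive pairs (bulges / internal loops), no multiloops,
# closed by a terminal hairpin loop of at least minLoop nt.  This is
# the structure class an intrinsic terminator occupies, and restricting
# to it keeps the dynamic programme exact and dependency-free while
# staying on the kcal/mol scale the -10 kcal/mol threshold assumes.

.MAX_SIDE <- 3L  # max unpaired nt per side between consecutive pairs

# Dynamic programme over the window.  C[i, j, s] = minimal free energy
# of a single-stem structure whose outermost pair is (i, j) and that
# contains at least s pairs (s capped at minStem).  Filled inner-to-
# outer; the final answer is min over (i, j) of C[i, j, minStem].
.hairpinDP <- function(code, params) {
  L <- length(code)
  S <- params@minStem
  minLoop <- params@minLoop
  C <- array(Inf, dim = c(L, L, S))
  if (L < minLoop + 2L) return(list(C = C, code = code))
  for (span in (minLoop + 1L):(L - 1L)) {
    for (i in seq_len(L - span)) {
      j <- i + span
      outer <- .pairCode[code[i], code[j]]
      if (outer == 0L) next
      hp <- if (span - 1L >= minLoop) .loopPenalty(span - 1L) else Inf
      best <- c(hp, rep(Inf, S - 1L))
      pmax_ <- min(i + .MAX_SIDE + 1L, j - 2L)
      for (p in (i + 1L):pmax_) {
        a <- p - i - 1L
        qmin <- max(j - .MAX_SIDE - 1L, p + 1L)
        for (q in qmin:(j - 1L)) {
          if (q <= p) next
          inner <- .pairCode[code[p], code[q]]
          if (inner == 0L) next
          b <- j - q - 1L
          tr <- .transDG(outer, inner, a, b)
          for (s in seq_len(S)) {
            v <- tr + C[p, q, if (s == 1L) 1L else s - 1L]
            if (v < best[s]) best[s] <- v
          }
        }
      }
      C[i, j, ] <- best
    }
  }
  list(C = C, code = code)
}

# Reconstruct the pair list of the optimum rooted at (i, j): re-derive
# each choice in a fixed order so ties resolve deterministically
# (stacked/5'-most inner pair first).
.hairpinTrace <- function(dp, i, j, params) {
  C <- dp$C; code <- dp$code
  S <- params@minStem
  minLoop <- params@minLoop
  pairs <- matrix(integer(0), ncol = 2)
  s <- S
  repeat {
    pairs <- rbind(pairs, c(i, j))
    outer <- .pairCode[code[i], code[j]]
    target <- C[i, j, s]
    hp <- if (j - i - 1L >= minLoop) .loopPenalty(j - i - 1L) else Inf
    if (s == 1L && isTRUE(all.equal(hp, target))) break
    found <- FALSE
    pmax_ <- min(i + .MAX_SIDE + 1L, j - 2L)
    for (p in (i + 1L):pmax_) {
      qmin <- max(j - .MAX_SIDE - 1L, p + 1L)
      for (q in (j - 1L):qmin) {  # smallest gap (stack) first
        if (q <= p) next
        inner <- .pairCode[code[p], code[q]]
        if (inner == 0L) next
        tr <- .transDG(outer, inner, p - i - 1L, j - q - 1L)
        s2 <- if (s == 1L) 1L else s - 1L
        if (is.finite(C[p, q, s2]) &&
            isTRUE(all.equal(tr + C[p, q, s2], target))) {
          i <- p; j <- q; s <- s2; found <- TRUE; break
        }
      }
      if (found) break
    }
    if (!found) break  # numerically exhausted; hairpin closes here
  }
  pairs
}

.toRnaCode <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "U"))
  codeT <- match(chars, c("A", "C", "G", "T"))
  code[is.na(code)] <- codeT[is.na(code)]
  if (anyNA(code))
    stopf("non-ACGT/U character '%s' in sequence",
          chars[which(is.na(code))[1]])
  code
}

#' Minimum-free-energy single stem-loop of a sequence
#'
#' Finds the most stable hairpin (single stem-loop, bulges/internal
#' loops up to 3 nt per side, no multiloops) under the packaged
#' nearest-neighbour parameters.  T and U are treated identically.
#' Among co-optimal folds the 5'-most, then shortest span is reported.
#'
#' @param sequence nucleotide string.
#' @param params a [TerminatorParams-class] (uses `minStem`, `minLoop`).
#' @param end3 optional position; when given, only folds whose 3'-most
#'   base sits exactly at `end3` are considered (used to anchor a
#'   hairpin at a fixed distance from a T-run).
#' @return `NULL` when no structure with at least `minStem` pairs
#'   exists, otherwise a list with elements `pairs` (2-column matrix of
#'   paired positions, outermost first), `dg` (kcal/mol), `span`
#'   (outermost pair positions), `loop` (innermost unpaired interval)
#'   and `dotBracket`.
#' @examples
#' bestHairpin("GGGGGAAAACCCCC")$dg
#' bestHairpin("AAAAAAAAAAAA")  # NULL: nothing can pair
#' @export
bestHairpin <- function(sequence, params = terminatorParams(),
                        end3 = NULL) {
  code <- .toRnaCode(sequence)
  dp <- .hairpinDP(code, params)
  .bestFromDP(dp, params, end3 = end3)
}

.bestFromDP <- function(dp, params, end3 = NULL) {
  S <- params@minStem
  M <- dp$C[, , S, drop = FALSE]
  dim(M) <- dim(dp$C)[1:2]
  if (!is.null(end3)) {
    keep <- matrix(Inf, nrow(M), ncol(M))
    if (end3 >= 1 && end3 <= ncol(M)) keep[, end3] <- M[, end3]
    M <- keep
  }
  if (!any(is.finite(M))) return(NULL)
  dg <- min(M)
  idx <- which(M == dg, arr.ind = TRUE)
  # 5'-most start, then shortest span
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- unname(idx[1, 1]); j <- unname(idx[1, 2])
  pairs <- .hairpinTrace(dp, i, j, params)
  inner <- pairs[nrow(pairs), ]
  db <- rep(".", length(dp$code))
  db[pairs[, 1]] <- "("
  db[pairs[, 2]] <- ")"
  list(pairs = pairs, dg = dg, span = c(i, j),
       loop = c(inner[1] + 1L, inner[2] - 1L),
       dotBracket = paste(db[i:j], collapse = ""))
}

# Free energy of an explicit single-stem pair list under the same
# parameter table (used by the planting code; tests carry their own
# independent implementation).
.scorePairList <- function(code, pairs, params) {
  k <- nrow(pairs)
  if (k < params@minStem) return(Inf)
  loopLen <- pairs[k, 2] - pairs[k, 1] - 1L
  if (loopLen < params@minLoop) return(Inf)
  e <- .loopPenalty(loopLen)
  if (k > 1L) for (r in seq_len(k - 1L)) {
    outer <- .pairCode[code[pairs[r, 1]], code[pairs[r, 2]]]
    inner <- .pairCode[code[pairs[r + 1L, 1]], code[pairs[r + 1L, 2]]]
    a <- pairs[r + 1L, 1] - pairs[r, 1] - 1L
    b <- pairs[r, 2] - pairs[r + 1L, 2] - 1L
    e <- e + .transDG(outer, inner, a, b)
  }
  e
}
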