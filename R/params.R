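#' Construct terminator detection parameters
#'
#' Defaults follow the canonical intrinsic-terminator heuristic: a 50-nt
#' analysis window downstream of the aptamer, a T-run of at least 5 T
#' residues within a 6-nt sliding window, a stem-loop with free energy
#' strictly below -10 kcal/mol, and at most 2 nt between the hairpin
#' base and the T-run.
#'
#' @param windowLen analysis window length, nt.
#' @param tRunMinT minimum number of T residues in the sliding window.
#' @param tRunWindow sliding window width, nt.
#' @param dgThreshold hairpin free-energy cutoff, kcal/mol (strict `<`).
#' @param maxGap maximum nt between hairpin 3' base and T-run start.
#' @param minStem minimum stem base pairs.
#' @param minLoop minimum hairpin loop length, nt.
#' @return a [TerminatorParams-class] object.
#' @examples
#' terminatorParams()
#' terminatorParams(windowLen = 60)
#' @export
terminatorParams <- function(windowLen = 50, tRunMinT = 5, tRunWindow = 6,
                             dgThreshold = -10, maxGap = 2, minStem = 3,
                             minLoop = 3) {
  new("TerminatorParams",
      windowLen = as.integer(windowLen), tRunMinT = as.integer(tRunMinT),
      tRunWindow = as.integer(tRunWindow), dgThreshold = as.numeric(dgThreshold),
      maxGap = as.integer(maxGap), minStem = as.integer(minStem),
      minLoop = as.integer(minLoop))
}

#' Construct architecture classification parameters
#'
#' The 20-nt default adjacency threshold encodes the observation that a
#' Rho-independent terminator needs at least ~20 nt between two aptamer
#' domains; junctions narrower than that cannot host a complete
#' expression platform and are classed as adjacent aptamers.
#'
#' @param adjacencyThreshold nt; gaps strictly below are `adjacent`.
#' @param overlapFrac overlap fraction (of the shorter hit) above which
#'   two hits are considered redundant during deduplication.
#' @return an [ArchParams-class] object.
#' @examples
#' archParams()
#' @export
archParams <- function(adjacencyThreshold = 20, overlapFrac = 0.5) {
  new("ArchParams", adjacencyThreshold = as.integer(adjacencyThreshold),
      overlapFrac = as.numeric(overlapFrac))
}

#' Construct shuffle-calibration parameters
#'
#' @param nShuffles dinucleotide-preserving shuffles per region
#'   (default 100).
#' @param seed root RNG seed.
#' @param floorBits cutoff reported when no random hit occurs (bits).
#' @return a [ShuffleParams-class] object.
#' @examples
#' shuffleParams(nShuffles = 10, seed = 1)
#' @export
shuffleParams <- function(nShuffles = 100, seed = 1, floorBits = 0) {
  new("ShuffleParams", nShuffles = as.integer(nShuffles),
      seed = as.integer(seed), floorBits = as.numeric(floorBits))
}

setMethod("show", "TerminatorParams", function(object) {
  cat("TerminatorParams: window", object@windowLen, "nt; T-run >=",
      object@tRunMinT, "T in", object@tRunWindow, "nt; dG <",
      object@dgThreshold, "kcal/mol; gap <=", object@maxGap,
      "nt; stem >=", object@minStem, "bp; loop >=", object@minLoop, "nt\n")
})

setMethod("show", "ArchParams", function(object) {
  cat("ArchParams: adjacency threshold", object@adjacencyThreshold,
      "nt (gap < threshold => adjacent); dedup overlap >",
      object@overlapFrac, "of shorter hit\n")
})

setMethod("show", "ShuffleParams", function(object) {
  cat("ShuffleParams:", object@nShuffles, "shuffles/region; seed",
      object@seed, "; cutoff floor", object@floorBits, "bits\n")
})
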