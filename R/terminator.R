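# Rho-independent (intrinsic) terminator detection: a T-run found by a
# sliding-window rule plus a stable hairpin ending at most maxGap nt
# before it.

#' Find T-runs in a sequence
#'
#' Slides a `tRunWindow`-nt window along the sequence, keeps every
#' placement containing at least `tRunMinT` T residues, merges
#' overlapping placements and clips each merged run to its first and
#' last T.  Runs are returned 5' to 3'.
#'
#' @param sequence nucleotide string (T or U).
#' @param params a [TerminatorParams-class].
#' @return a data.frame with columns `start`, `end` (1-based inclusive),
#'   zero rows when no run qualifies.
#' @examples
#' findTRuns("AATTTTTAA")    # one run over the 5 T's
#' findTRuns("AAAAAAAA")     # none
#' @export
findTRuns <- function(sequence, params = terminatorParams()) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  isT <- as.integer(chars %in% c("T", "U"))
  n <- length(isT)
  w <- params@tRunWindow
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < params@tRunMinT) return(empty)
  if (n < w) {
    # shorter than one window: accept the whole sequence if it has
    # enough T residues
    if (sum(isT) >= params@tRunMinT) wins <- IRanges::IRanges(1L, n)
    else return(empty)
  } else {
    cs <- c(0L, cumsum(isT))
    starts <- seq_len(n - w + 1L)
    counts <- cs[starts + w] - cs[starts]
    hit <- starts[counts >= params@tRunMinT]
    if (!length(hit)) return(empty)
    wins <- IRanges::IRanges(hit, hit + w - 1L)
  }
  merged <- IRanges::reduce(wins)
  out <- data.frame(start = IRanges::start(merged),
                    end = IRanges::end(merged))
  # clip each run to its T content
  for (r in seq_len(nrow(out))) {
    idx <- out$start[r]:out$end[r]
    ts <- idx[isT[idx] == 1L]
    out$start[r] <- min(ts); out$end[r] <- max(ts)
  }
  out
}

#' Call an intrinsic terminator downstream of an aptamer
#'
#' Scans the `windowLen`-nt window starting right after `aptamerEnd`
#' (clipped to the region and, optionally, to `limit`).  For each
#' T-run, 5' to 3', the most stable stem-loop of the window portion
#' preceding the run is determined (in an intrinsic terminator the
#' U-tail is single-stranded, so structure downstream of the run never
#' competes); a call requires that hairpin to clear the free-energy
#' threshold (strictly below `dgThreshold`) and to end at most
#' `maxGap` nt before the run start.  Co-optimal hairpins are resolved
#' toward the run (smallest gap, then 5'-most).  The first T-run with
#' a qualifying hairpin wins.  Requiring the *most stable* structure
#' before the run, not merely any sufficiently stable one, keeps the
#' detector specific on shuffled sequence.  Coordinates in the
#' returned call are positions in the supplied region sequence.
#'
#' @param region an [IntergenicRegionSet-class] of length 1, or a plain
#'   transcript-oriented nucleotide string.
#' @param aptamerEnd 1-based position of the aptamer's last nucleotide
#'   within the region.
#' @param params a [TerminatorParams-class].
#' @param limit optional last position (inclusive) the window may reach,
#'   e.g. one before the next aptamer's start.
#' @param aptamerRef identifier copied into the call.
#' @return `NULL`, or a one-row data.frame with columns `aptamer_ref`,
#'   `t_run_start`, `t_run_end`, `hairpin_start`, `hairpin_end`, `gap`,
#'   `dg`, `structure` (dot-bracket of the hairpin span).
#' @export
callTerminator <- function(region, aptamerEnd, params = terminatorParams(),
                           limit = NULL, aptamerRef = NA_character_) {
  seqStr <- if (is(region, "IntergenicRegionSet")) {
    stopifnot(length(region) == 1L)
    as.character(regionSeqs(region))[[1]]
  } else as.character(region)
  n <- nchar(seqStr)
  if (aptamerEnd < 0L || aptamerEnd >= n) return(NULL)
  wStart <- aptamerEnd + 1L
  wEnd <- min(aptamerEnd + params@windowLen, n)
  if (!is.null(limit)) wEnd <- min(wEnd, limit)
  if (wEnd - wStart + 1L < 2L * params@minStem + params@minLoop +
      params@tRunMinT) return(NULL)
  window <- substr(seqStr, wStart, wEnd)
  runs <- findTRuns(window, params)
  if (!nrow(runs)) return(NULL)
  dp <- .hairpinDP(.toRnaCode(window), params)
  # best energy of a hairpin ending exactly at e, for every e
  S <- params@minStem
  anch <- apply(dp$C[, , S, drop = FALSE], 2, min)
  for (r in seq_len(nrow(runs))) {
    if (runs$start[r] < 2L) next
    prefixBest <- min(anch[seq_len(runs$start[r] - 1L)])
    if (!is.finite(prefixBest) || prefixBest >= params@dgThreshold) next
    for (g in 0:params@maxGap) {
      e <- runs$start[r] - 1L - g
      if (e < 2L * params@minStem + params@minLoop) break
      if (!is.finite(anch[e]) || anch[e] >= params@dgThreshold) next
      # only a most-stable stem-loop of the pre-run prefix may call
      if (anch[e] > prefixBest + 1e-9) next
      fold <- .bestFromDP(dp, params, end3 = e)
      off <- wStart - 1L
      return(data.frame(
        aptamer_ref = aptamerRef,
        t_run_start = runs$start[r] + off, t_run_end = runs$end[r] + off,
        hairpin_start = fold$span[1] + off, hairpin_end = fold$span[2] + off,
        gap = g, dg = fold$dg, structure = fold$dotBracket,
        stringsAsFactors = FALSE))
    }
  }
  NULL
}

#' Scan inter-aptamer junctions of contiguous groups for terminators
#'
#' For every group with at least two aptamers, [callTerminator()] is
#' applied after each non-final aptamer, with the analysis window
#' clipped so it never reads into the next aptamer.  A terminator here
#' is the expression platform of a complete upstream riboswitch unit,
#' i.e. the evidence for a tandem arrangement.
#'
#' @param groups a [ContiguousGroupSet-class] (see [groupContiguous()]).
#' @param regions the [IntergenicRegionSet-class] the groups live on.
#' @param params a [TerminatorParams-class].
#' @return a data.frame of terminator calls (zero rows when none), one
#'   per junction with a qualifying call, with `region_ref` and
#'   `junction` columns added to the [callTerminator()] fields.
#' @export
scanInterAptamer <- function(groups, regions,
                             params = terminatorParams()) {
  apt <- groups@aptamers
  out <- list()
  seqs <- as.character(regionSeqs(regions))
  ids <- regionIds(regions)
  for (gidx in seq_len(nrow(groups@groups))) {
    members <- apt[apt$group == gidx]
    if (length(members) < 2L) next
    members <- members[order(GenomicRanges::start(members))]
    region <- as.character(groups@groups$region_ref[gidx])
    sidx <- match(region, ids)
    if (is.na(sidx)) stopf("region '%s' absent from region set", region)
    sq <- seqs[[sidx]]
    for (k in seq_len(length(members) - 1L)) {
      call <- callTerminator(
        sq, GenomicRanges::end(members)[k], params,
        limit = GenomicRanges::start(members)[k + 1L] - 1L,
        aptamerRef = members$hit_id[k])
      if (!is.null(call)) {
        call$region_ref <- region
        call$junction <- k
        out[[length(out) + 1L]] <- call
      }
    }
  }
  if (!length(out))
    return(data.frame(aptamer_ref = character(0), t_run_start = integer(0),
                      t_run_end = integer(0), hairpin_start = integer(0),
                      hairpin_end = integer(0), gap = integer(0),
                      dg = numeric(0), structure = character(0),
                      region_ref = character(0), junction = integer(0)))
  do.call(rbind, out)
}
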