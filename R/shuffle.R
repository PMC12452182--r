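# Dinucleotide-preserving shuffling (Altschul-Erickson Euler-path
# construction) and empirical bit-score cutoff calibration.

.DNA <- c("A", "C", "G", "T")

.encodeDna <- function(sequence) {
  if (!isScalarString(sequence)) stopf("sequence must be a single string")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- match(chars, .DNA)
  if (anyNA(code))
    stopf("non-ACGT character '%s' at position %d",
          chars[which(is.na(code))[1]], which(is.na(code))[1])
  code
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Produces a random sequence with exactly the input's multiset of
#' overlapping dinucleotides, via the Euler-path construction on the
#' dinucleotide multigraph: a random "last edge" is reserved for every
#' vertex so that the reserved edges form a tree into the final
#' nucleotide (guaranteeing an Eulerian walk exists), the remaining
#' edges are ordered randomly, and the walk is read off.  The output
#' therefore preserves length, mononucleotide counts, the first and
#' last letter, and every dinucleotide count.  Non-ACGT characters are
#' rejected; hard-mask or trim ambiguous regions upstream.
#'
#' @param sequence a single ACGT string, length >= 2.
#' @param seed optional integer; when given the shuffle is a pure
#'   function of `(sequence, seed)` and the caller's RNG state is left
#'   untouched.
#' @return a shuffled string of the same length.
#' @examples
#' dinucleotideShuffle("GAATTC", seed = 1)
#' dinucleotideShuffle("AAAA")  # unique sequence with that multiset
#' @export
dinucleotideShuffle <- function(sequence, seed = NULL) {
  if (!is.null(seed))
    return(withSeed(seed, dinucleotideShuffle(sequence)))
  code <- .encodeDna(sequence)
  n <- length(code)
  if (n < 2L) stopf("sequence must have length >= 2")
  first <- code[1]; last <- code[n]
  # out-edge target multisets
  edges <- vector("list", 4L)
  from <- code[-n]; to <- code[-1]
  for (v in 1:4) edges[[v]] <- to[from == v]
  present <- which(lengths(edges) > 0L | seq_len(4) == last)
  if (length(present) == 1L) return(sequence)  # e.g. homopolymer

  for (attempt in seq_len(10000L)) {
    # reserve a random last edge per vertex (except the terminal one)
    lastEdge <- rep(NA_integer_, 4L)
    for (v in present) {
      if (v == last || !length(edges[[v]])) next
      lastEdge[v] <- edges[[v]][sample.int(length(edges[[v]]), 1L)]
    }
    # reserved edges must form a tree into `last`
    ok <- TRUE
    for (v in present) {
      if (v == last || is.na(lastEdge[v])) next
      seen <- integer(0); cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(lastEdge[cur])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- lastEdge[cur]
      }
      if (!ok) break
    }
    if (!ok) next
    # random order of the remaining edges, reserved edge last
    queue <- vector("list", 4L)
    for (v in 1:4) {
      e <- edges[[v]]
      if (!is.na(lastEdge[v])) {
        drop <- match(lastEdge[v], e)
        e <- e[-drop]
      }
      if (length(e) > 1L) e <- e[sample.int(length(e))]
      if (!is.na(lastEdge[v])) e <- c(e, lastEdge[v])
      queue[[v]] <- e
    }
    # Eulerian walk
    out <- integer(n); out[1] <- first
    ptr <- rep(1L, 4L); cur <- first
    for (i in 2:n) {
      nxt <- queue[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    return(paste(.DNA[out], collapse = ""))
  }
  stopf("failed to construct an Eulerian shuffle (degenerate input?)")
}

#' Calibrate an empirical bit-score cutoff from shuffled regions
#'
#' Every intergenic region is shuffled `nShuffles` times with the
#' dinucleotide-preserving shuffler and each shuffle is scanned with the
#' supplied scoring oracle; the cutoff is the highest score any random
#' sequence attains (the score noise can reach by construction).  When
#' no random hit occurs at all the configured floor is reported, so a
#' curated gathering threshold supplied by the caller can dominate.
#' Per-(region, replicate) RNG substreams are derived from the root
#' seed, making the result independent of evaluation order and
#' monotone: adding regions can only raise the cutoff.
#'
#' @param modelName covariance-model name the cutoff is for.
#' @param regions an [IntergenicRegionSet-class] or named character
#'   vector of sequences.
#' @param scanner `function(sequence)` returning the bit scores of the
#'   model's hits on that sequence (numeric, possibly empty; a
#'   data.frame with a `score` column is also accepted).  Must be
#'   deterministic given the sequence.
#' @param params a [ShuffleParams-class].
#' @param mode `"region"` (default): shuffle each region's own
#'   sequence, preserving its length and local dinucleotide statistics;
#'   `"genome"`: sample length-matched sequences from the first-order
#'   Markov model pooled over all regions.
#' @return one-row data.frame: `model_name`, `cutoff_bits`,
#'   `n_random_hits`.
#' @seealso [applyCutoffs()]
#' @export
calibrateCutoff <- function(modelName, regions, scanner,
                            params = shuffleParams(),
                            mode = c("region", "genome")) {
  mode <- match.arg(mode)
  seqs <- if (is(regions, "IntergenicRegionSet"))
    as.character(regionSeqs(regions)) else as.character(regions)
  if (!length(seqs)) stopf("calibrateCutoff: empty region collection")
  trans <- if (mode == "genome") .dinucTransitions(seqs) else NULL
  best <- -Inf; nHits <- 0L
  for (i in seq_along(seqs)) {
    for (r in seq_len(params@nShuffles)) {
      sd <- deriveSeed(params@seed, i, r)
      rand <- if (mode == "region")
        dinucleotideShuffle(seqs[[i]], seed = sd)
      else withSeed(sd, .sampleMarkov(nchar(seqs[[i]]), trans))
      sc <- scanner(rand)
      if (is.data.frame(sc)) sc <- sc$score
      sc <- as.numeric(sc)
      if (length(sc)) {
        nHits <- nHits + length(sc)
        best <- max(best, sc)
      }
    }
  }
  data.frame(model_name = modelName,
             cutoff_bits = if (nHits > 0L) best else params@floorBits,
             n_random_hits = nHits)
}

# Pooled first-order Markov model of a sequence collection.
.dinucTransitions <- function(seqs) {
  counts <- matrix(1e-9, 4, 4, dimnames = list(.DNA, .DNA))
  starts <- numeric(4); names(starts) <- .DNA
  for (s in seqs) {
    code <- .encodeDna(s)
    starts[code[1]] <- starts[code[1]] + 1
    if (length(code) > 1L)
      for (i in seq_len(length(code) - 1L))
        counts[code[i], code[i + 1L]] <- counts[code[i], code[i + 1L]] + 1
  }
  list(init = starts / sum(starts),
       trans = counts / rowSums(counts))
}

.sampleMarkov <- function(len, model) {
  out <- integer(len)
  out[1] <- sample.int(4L, 1L, prob = model$init)
  if (len > 1L)
    for (i in 2:len)
      out[i] <- sample.int(4L, 1L, prob = model$trans[out[i - 1L], ])
  paste(.DNA[out], collapse = "")
}

#' Filter aptamer hits by empirical cutoffs
#'
#' Hits scoring strictly above their model's empirical cutoff survive
#' (the cutoff itself is attainable by noise, so equality is removed).
#' Hits of models without a calibrated cutoff are retained unchanged and
#' flagged via the `cutoff_applied` column.
#'
#' @param hits a hit `GRanges` (see [readTblout()]).
#' @param cutoffs data.frame with columns `model_name`, `cutoff_bits`
#'   (rows from [calibrateCutoff()]), or a named numeric vector.
#' @return the filtered `GRanges`, with logical mcol `cutoff_applied`.
#' @export
applyCutoffs <- function(hits, cutoffs) {
  if (is.data.frame(cutoffs))
    cutoffs <- setNames(cutoffs$cutoff_bits, cutoffs$model_name)
  cut <- unname(cutoffs[hits$model_class])
  hits$cutoff_applied <- !is.na(cut)
  keep <- is.na(cut) | hits$bit_score > cut
  hits[keep]
}
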