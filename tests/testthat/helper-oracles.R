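# Independent oracles used by the unit and acceptance tests.  Each is
# deliberately written as a brute-force method that shares no code
# path with the implementation it checks (the hairpin oracle shares
# only the published parameter table).

# Overlapping dinucleotide multiset of a sequence, as a sorted
# character vector.
oracleDinucs <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(ch) < 2) return(character(0))
  sort(paste0(ch[-length(ch)], ch[-1]))
}

# All sequences with the same length, first and last letter, and
# dinucleotide multiset as `s` (feasible for nchar(s) <= 8): permute
# the interior letters and filter on the dinucleotide multiset.
oracleShuffleSet <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n <= 2) return(s)
  mid <- ch[2:(n - 1)]
  perms <- unique(combinat_perms(mid))
  cand <- vapply(perms, function(p)
    paste(c(ch[1], p, ch[n]), collapse = ""), character(1))
  ref <- oracleDinucs(s)
  unique(cand[vapply(cand, function(x)
    identical(oracleDinucs(x), ref), logical(1))])
}

# All permutations of a character vector (multiset-aware recursion).
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in combinat_perms(rest)) out[[length(out) + 1]] <- c(v, p)
  }
  out
}

# Brute-force upper-tail hypergeometric probability by direct
# summation of choose() terms.
oracleHyper <- function(N, K, n, k) {
  jmax <- min(n, K)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# --- exhaustive single-stem enumeration oracle -----------------------
# Enumerates every legal single-stem structure (nested pairs, at most 3
# unpaired nt per side between consecutive pairs, >= minStem pairs,
# terminal loop >= minLoop) of a short sequence and scores it with its
# own reading of the published parameter table.  Returns the minimal
# free energy, or Inf when no structure exists.

.oPairs <- local({
  m <- matrix(0L, 4, 4, dimnames = rep(list(c("A", "C", "G", "U")), 2))
  m["A", "U"] <- 1L; m["U", "A"] <- 2L; m["C", "G"] <- 3L
  m["G", "C"] <- 4L; m["G", "U"] <- 5L; m["U", "G"] <- 6L
  m
})

.oStack <- matrix(c(
  -0.93, -1.10, -2.24, -2.08, -0.55, -1.36,
  -1.33, -0.93, -2.35, -2.11, -1.27, -1.00,
  -2.11, -2.08, -3.26, -2.36, -1.41, -2.11,
  -2.35, -2.24, -3.42, -3.26, -1.53, -2.51,
  -1.36, -1.00, -2.51, -2.11, -0.50,  1.29,
  -0.55, -1.27, -1.53, -1.41,  0.30, -0.50), 6, 6, byrow = TRUE)

.oHairpin <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)
.oBulge <- c(3.8, 2.8, 3.2)
.oInternal <- c(1.0, 1.8, 2.0, 2.2, 2.5)

oracleLoopPen <- function(len) {
  if (len <= 9) .oHairpin[max(len, 3) - 2]
  else .oHairpin[7] + 1.75 * 0.6163 * log(len / 9)
}

oracleScoreStem <- function(code, pairs, minLoop = 3) {
  k <- nrow(pairs)
  loopLen <- pairs[k, 2] - pairs[k, 1] - 1
  if (loopLen < minLoop) return(Inf)
  e <- oracleLoopPen(loopLen)
  if (k > 1) for (r in seq_len(k - 1)) {
    outer <- .oPairs[code[pairs[r, 1]], code[pairs[r, 2]]]
    inner <- .oPairs[code[pairs[r + 1, 1]], code[pairs[r + 1, 2]]]
    a <- pairs[r + 1, 1] - pairs[r, 1] - 1
    b <- pairs[r, 2] - pairs[r + 1, 2] - 1
    e <- e + if (a == 0 && b == 0) .oStack[outer, inner]
      else if (a == 0 || b == 0) .oBulge[a + b]
      else .oInternal[a + b - 1] + 0.6 * abs(a - b)
  }
  unname(e)
}

# Depth-first enumeration of all stems; returns min energy over
# structures with >= minStem pairs.
oracleBestHairpin <- function(sequence, minStem = 3, minLoop = 3,
                              maxSide = 3) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  ch[ch == "T"] <- "U"
  n <- length(ch)
  best <- Inf
  recurse <- function(pairs) {
    k <- nrow(pairs)
    if (k >= minStem) {
      e <- oracleScoreStem(ch, pairs, minLoop)
      if (e < best) best <<- e
    }
    i <- pairs[k, 1]; j <- pairs[k, 2]
    pmax <- min(i + maxSide + 1, j - 2)
    if (pmax < i + 1) return(invisible())
    for (p in (i + 1):pmax) {
      qmin <- max(j - maxSide - 1, p + 1)
      if (qmin > j - 1) next
      for (q in (j - 1):qmin) {
        if (.oPairs[ch[p], ch[q]] == 0L) next
        recurse(rbind(pairs, c(p, q)))
      }
    }
  }
  if (n >= minLoop + 2) {
    for (i in 1:(n - minLoop - 1)) {
      for (j in (i + minLoop + 1):n) {
        if (.oPairs[ch[i], ch[j]] == 0L) next
        recurse(matrix(c(i, j), 1, 2))
      }
    }
  }
  best
}

# Random ACGT string.
randSeq <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Build a gene-table TSV on disk from a data.frame of 0-based
# half-open rows.
writeGeneTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  header <- c("genome_id", "species", "phylum", "contig", "start",
              "end", "strand", "gene_id", "cog_id")
  lines <- c(paste(header, collapse = "\t"),
             apply(df[header], 1, paste, collapse = "\t"))
  writeLines(lines, path)
  path
}

geneRow <- function(genome = "gA", species = "sp1", phylum = "PhyX",
                    contig = "c1", start = 0, end = 10, strand = "+",
                    gene = "g1", cog = "") {
  data.frame(genome_id = genome, species = species, phylum = phylum,
             contig = contig, start = start, end = end, strand = strand,
             gene_id = gene, cog_id = cog, stringsAsFactors = FALSE)
}

# Minimal hit GRanges builder for architecture tests.
makeHits <- function(region, starts, ends, models, scores,
                     evalues = NULL, genome = "gA") {
  if (is.null(evalues)) evalues <- 10^-(scores / 4)
  GenomicRanges::GRanges(
    seqnames = region,
    ranges = IRanges::IRanges(starts, ends), strand = "+",
    hit_id = paste0(region, ":", starts, "-", ends, ":", models),
    model_class = models, model_acc = "-",
    bit_score = scores, evalue = evalues, region_ref = region)
}

# Region set with a single literal sequence.
makeRegion <- function(seq, id = "igr|gA|g1", genome = "gA",
                       gene = "g1") {
  gr <- GenomicRanges::GRanges(
    seqnames = id, ranges = IRanges::IRanges(1L, nchar(seq)),
    strand = "+", region_id = id, genome_id = genome,
    downstream_gene_id = gene)
  sq <- Biostrings::DNAStringSet(seq)
  names(sq) <- id
  new("IntergenicRegionSet", ranges = gr, seq = sq)
}
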