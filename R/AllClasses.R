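#' @import methods
NULL

#' Parameters for intrinsic terminator detection
#'
#' Bundles the tunable constants of the Rho-independent terminator
#' detector: the length of the analysis window scanned downstream of an
#' aptamer, the T-run rule (a sliding window of `tRunWindow` nt must
#' contain at least `tRunMinT` T residues), the free-energy threshold the
#' hairpin must beat (strictly below `dgThreshold`, in kcal/mol at 37
#' degrees C), the maximum spacer allowed between the hairpin base and
#' the T-run, and the minimal stem/loop geometry of the hairpin fold.
#'
#' @slot windowLen integer, analysis window length in nt (default 50).
#' @slot tRunMinT integer, minimum T count inside the sliding window
#'   (default 5).
#' @slot tRunWindow integer, sliding window width in nt (default 6).
#' @slot dgThreshold numeric, hairpin free-energy cutoff in kcal/mol;
#'   calls require dG strictly less than this (default -10).
#' @slot maxGap integer, maximum nt between the hairpin 3' base and the
#'   T-run start (default 2).
#' @slot minStem integer, minimum base pairs in the stem (default 3).
#' @slot minLoop integer, minimum hairpin loop length in nt (default 3).
#' @seealso [terminatorParams()]
#' @exportClass TerminatorParams
setClass("TerminatorParams",
  representation(
    windowLen = "integer", tRunMinT = "integer", tRunWindow = "integer",
    dgThreshold = "numeric", maxGap = "integer", minStem = "integer",
    minLoop = "integer"
  )
)

setValidity("TerminatorParams", function(object) {
  msg <- character()
  if (object@windowLen < 1L) msg <- c(msg, "windowLen must be positive")
  if (object@dgThreshold >= 0) msg <- c(msg, "dgThreshold must be negative")
  if (object@maxGap < 0L) msg <- c(msg, "maxGap must be >= 0")
  if (object@tRunMinT < 1L || object@tRunWindow < object@tRunMinT)
    msg <- c(msg, "need 1 <= tRunMinT <= tRunWindow")
  if (object@minStem < 1L || object@minLoop < 1L)
    msg <- c(msg, "minStem and minLoop must be positive")
  if (length(msg)) msg else TRUE
})

#' Parameters for contiguous-group construction and classification
#'
#' @slot adjacencyThreshold integer, nt; junctions with an inter-aptamer
#'   gap strictly below this are labelled `adjacent`, all others
#'   `tandem` (default 20).
#' @slot overlapFrac numeric in (0, 1]; two hits on the same region are
#'   considered redundant when their overlap exceeds this fraction of
#'   the shorter hit (default 0.5).
#' @seealso [archParams()]
#' @exportClass ArchParams
setClass("ArchParams",
  representation(adjacencyThreshold = "integer", overlapFrac = "numeric")
)

setValidity("ArchParams", function(object) {
  msg <- character()
  if (object@adjacencyThreshold < 0L)
    msg <- c(msg, "adjacencyThreshold must be >= 0")
  if (!isScalarNumber(object@overlapFrac) ||
      object@overlapFrac <= 0 || object@overlapFrac > 1)
    msg <- c(msg, "overlapFrac must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Parameters for dinucleotide-shuffle score calibration
#'
#' @slot nShuffles integer, number of dinucleotide-preserving shuffles
#'   generated per intergenic region (default 100).
#' @slot seed integer, root seed; per-(region, replicate) substreams are
#'   derived from it deterministically.
#' @slot floorBits numeric, cutoff reported when no random hit occurs at
#'   all (default 0 bits).
#' @seealso [shuffleParams()]
#' @exportClass ShuffleParams
setClass("ShuffleParams",
  representation(nShuffles = "integer", seed = "integer",
                 floorBits = "numeric")
)

setValidity("ShuffleParams", function(object) {
  if (object@nShuffles < 1L) "nShuffles must be >= 1" else TRUE
})

#' A set of intergenic regions with their sequences
#'
#' Couples the genomic coordinates of strand-aware upstream intergenic
#' regions (a [GenomicRanges::GRanges] with metadata columns
#' `region_id`, `genome_id` and `downstream_gene_id`; the range strand is
#' the transcription direction of the downstream gene) with their
#' nucleotide sequences (a [Biostrings::DNAStringSet] named by
#' `region_id`).  Minus-strand sequences are stored reverse-complemented,
#' so within every stored sequence position increases toward the
#' downstream gene's start codon and all windowing downstream of an
#' aptamer is orientation-free.
#'
#' @slot ranges `GRanges` of the regions in genome coordinates.
#' @slot seq `DNAStringSet` of transcript-oriented sequences, parallel to
#'   and named like `ranges$region_id`.
#' @seealso [extractIntergenic()], [regionSeqs()], [regionRanges()]
#' @exportClass IntergenicRegionSet
setClass("IntergenicRegionSet",
  representation(ranges = "GRanges", seq = "DNAStringSet")
)

setValidity("IntergenicRegionSet", function(object) {
  r <- object@ranges
  s <- object@seq
  msg <- character()
  need <- c("region_id", "genome_id", "downstream_gene_id")
  miss <- setdiff(need, colnames(S4Vectors::mcols(r)))
  if (length(miss))
    msg <- c(msg, paste("missing mcols:", paste(miss, collapse = ", ")))
  else {
    if (length(r) != length(s))
      msg <- c(msg, "ranges and seq lengths differ")
    else {
      if (length(r) && !identical(names(s), as.character(r$region_id)))
        msg <- c(msg, "seq names must equal ranges$region_id")
      if (any(BiocGenerics::width(r) != BiocGenerics::width(s)))
        msg <- c(msg, "sequence widths must match range widths")
    }
    if (anyDuplicated(r$region_id))
      msg <- c(msg, "region_id values must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Contiguous riboswitch groups with architecture labels
#'
#' One row per intergenic region holding at least one aptamer hit.  The
#' `groups` table carries, per group: the region and regulated gene,
#' aptamer count, the 5'-to-3' family string, inter-aptamer junction
#' gaps and their tandem/adjacent labels, the overall group class
#' (`single`, `tandem`, `adjacent` or `mixed`), ligand homogeneity
#' (`homogeneous`, `heterogeneous` or `n/a`) and per-junction terminator
#' evidence.  The member hits are kept as a `GRanges` (`aptamers`) in
#' region coordinates with a `group` index column.
#'
#' @slot groups a [S4Vectors::DataFrame] with list-columns for junction
#'   data (see [groupTable()]).
#' @slot aptamers `GRanges` of member aptamer hits, region coordinates.
#' @seealso [groupContiguous()], [classifyGroups()], [groupTable()]
#' @exportClass ContiguousGroupSet
setClass("ContiguousGroupSet",
  representation(groups = "DataFrame", aptamers = "GRanges")
)

setValidity("ContiguousGroupSet", function(object) {
  g <- object@groups
  msg <- character()
  need <- c("region_ref", "n_aptamers", "junction_gaps", "junction_classes",
            "group_class", "homogeneity", "architecture_string")
  miss <- setdiff(need, colnames(g))
  if (length(miss))
    return(paste("missing group columns:", paste(miss, collapse = ", ")))
  n <- g$n_aptamers
  if (any(lengths(g$junction_gaps) != pmax(n - 1L, 0L)))
    msg <- c(msg, "junction_gaps must have n_aptamers - 1 entries")
  if (any((g$group_class == "single") != (n == 1L)))
    msg <- c(msg, "group_class 'single' iff exactly one aptamer")
  arch_n <- lengths(strsplit(ifelse(g$architecture_string == "", NA,
                                    g$architecture_string), " ", fixed = TRUE))
  if (any(!is.na(arch_n) & arch_n != n))
    msg <- c(msg, "architecture_string token count must equal n_aptamers")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic genome-collection generator
#'
#' Defines the study conditions a simulated collection emulates:
#' taxonomy size, per-genome gene counts, background sequence
#' composition, the per-gene riboswitch rate and its per-phylum
#' multipliers, the architecture mix of planted contiguous groups,
#' family weights, per-COG regulation multipliers, terminator planting
#' and the junction-gap ranges that keep planted architectures clear of
#' the 20-nt classification boundary.
#'
#' @slot nPhyla integer, number of phyla.
#' @slot genomesPerPhylum integer.
#' @slot genesPerGenome integer.
#' @slot meanIntergenicLen integer, nt, background (unregulated) regions.
#' @slot baseRiboswitchRate numeric, per-gene probability of regulation.
#' @slot phylumRateMultipliers numeric vector (length `nPhyla` or 1).
#' @slot architectureMix named numeric over
#'   `single`, `tandem_pair`, `adjacent_pair`, `tandem_triple`; sums to 1.
#' @slot familyWeights named numeric, sampling weights of planted
#'   riboswitch families; sums to 1.
#' @slot cogPool character, COG identifiers assigned to genes.
#' @slot cogEnrichment named numeric, per-COG multipliers on the
#'   regulated fraction (names must be in `cogPool`).
#' @slot terminatorPlantProb numeric, probability that a tandem junction
#'   receives the canonical planted terminator.
#' @slot tandemGapRange integer length-2, nt range of tandem junction
#'   gaps (must sit above the adjacency threshold with margin).
#' @slot adjacentGapRange integer length-2, nt range of adjacent
#'   junction gaps (must sit below the threshold).
#' @slot gcContent numeric in (0,1), background Markov-chain GC.
#' @slot seed integer, root seed.
#' @seealso [simConfig()], [simulateCollection()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nPhyla = "integer", genomesPerPhylum = "integer",
    genesPerGenome = "integer", meanIntergenicLen = "integer",
    baseRiboswitchRate = "numeric", phylumRateMultipliers = "numeric",
    architectureMix = "numeric", familyWeights = "numeric",
    cogPool = "character", cogEnrichment = "numeric",
    terminatorPlantProb = "numeric", tandemGapRange = "integer",
    adjacentGapRange = "integer", gcContent = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  mix <- object@architectureMix
  needMix <- c("single", "tandem_pair", "adjacent_pair", "tandem_triple")
  if (!setequal(names(mix), needMix))
    msg <- c(msg, "architectureMix needs exactly the four architecture names")
  else if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    msg <- c(msg, "architectureMix must be non-negative and sum to 1")
  if (any(object@familyWeights < 0) ||
      abs(sum(object@familyWeights) - 1) > 1e-8)
    msg <- c(msg, "familyWeights must be non-negative and sum to 1")
  if (is.null(names(object@familyWeights)))
    msg <- c(msg, "familyWeights must be named by family")
  if (object@baseRiboswitchRate < 0 || object@baseRiboswitchRate > 1)
    msg <- c(msg, "baseRiboswitchRate must be a probability")
  if (object@terminatorPlantProb < 0 || object@terminatorPlantProb > 1)
    msg <- c(msg, "terminatorPlantProb must be a probability")
  if (!length(object@phylumRateMultipliers) %in% c(1L, object@nPhyla))
    msg <- c(msg, "phylumRateMultipliers must have length 1 or nPhyla")
  thr <- 20L  # default classification threshold the gap ranges must respect
  if (object@tandemGapRange[1] <= thr)
    msg <- c(msg, "tandemGapRange lower bound must exceed the 20-nt threshold")
  if (object@adjacentGapRange[2] >= thr)
    msg <- c(msg, "adjacentGapRange upper bound must be below the 20-nt threshold")
  if (diff(object@tandemGapRange) < 0 || diff(object@adjacentGapRange) < 0)
    msg <- c(msg, "gap ranges must be non-decreasing")
  if (length(setdiff(names(object@cogEnrichment), object@cogPool)))
    msg <- c(msg, "cogEnrichment names must be drawn from cogPool")
  if (object@gcContent <= 0 || object@gcContent >= 1)
    msg <- c(msg, "gcContent must be in (0, 1)")
  if (length(msg)) msg else TRUE
})
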