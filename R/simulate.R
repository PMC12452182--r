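# Synthetic genome-collection generator with planted ground truth.
# Emulates the statistical structure the analyses assume: per-phylum
# riboswitch rates, per-COG regulation multipliers, per-family
# architecture propensities, planted contiguous architectures with
# junction gaps clear of the classification boundary, and canonical
# intrinsic terminators at tandem junctions.

.ARCH_ARITY <- c(single = 1L, tandem_pair = 2L, adjacent_pair = 2L,
                 tandem_triple = 3L)
.ARCH_CLASS <- c(single = "single", tandem_pair = "tandem",
                 adjacent_pair = "adjacent", tandem_triple = "tandem")

# The canonical planted terminator: 8-bp G:C stem, 4-nt loop, 8-nt
# T-tail.  dG of the stem is far below -10 kcal/mol under the packaged
# parameters, and the T-tail satisfies the >=5-T-in-6-nt run rule, so
# detection under default TerminatorParams is guaranteed by
# construction (and asserted in tests).
.TERM_ELEMENT <- paste0(strrep("G", 8), "AAAA", strrep("C", 8),
                        strrep("T", 8))

#' Construct a synthetic-collection configuration
#'
#' Defaults describe a desk-scale collection: 5 phyla x 4 genomes x
#' 200 genes with a 5% per-gene regulation rate, an architecture mix
#' dominated by single riboswitches but with a substantial contiguous
#' fraction, tandem junction gaps of 30-50 nt (safely above the 20-nt
#' adjacency threshold and wide enough for the 28-nt canonical
#' terminator), adjacent gaps of 5-15 nt (safely below), and
#' terminators planted at every tandem junction.
#'
#' @param nPhyla,genomesPerPhylum,genesPerGenome collection dimensions.
#' @param meanIntergenicLen nt, typical unregulated intergenic length.
#' @param baseRiboswitchRate per-gene probability of riboswitch
#'   regulation.
#' @param phylumRateMultipliers numeric, per-phylum fold on the base
#'   rate (length 1 or `nPhyla`).
#' @param architectureMix named probabilities over `single`,
#'   `tandem_pair`, `adjacent_pair`, `tandem_triple`.
#' @param familyWeights named sampling weights of planted families.
#' @param cogPool COG identifiers genes are drawn from.
#' @param cogEnrichment named per-COG multipliers on the regulation
#'   rate.
#' @param terminatorPlantProb probability a tandem junction receives
#'   the canonical terminator.
#' @param tandemGapRange,adjacentGapRange junction gap ranges, nt.
#' @param gcContent background GC fraction.
#' @param seed root seed; every random choice derives from it.
#' @return a [SimConfig-class].
#' @examples
#' simConfig(seed = 7)
#' @export
simConfig <- function(nPhyla = 5, genomesPerPhylum = 4,
                      genesPerGenome = 200, meanIntergenicLen = 120,
                      baseRiboswitchRate = 0.05,
                      phylumRateMultipliers = 1,
                      architectureMix = c(single = 0.55,
                                          tandem_pair = 0.20,
                                          adjacent_pair = 0.15,
                                          tandem_triple = 0.10),
                      familyWeights = c(`T-box` = 0.30, TPP = 0.15,
                                        SAM = 0.15, FMN = 0.10,
                                        Glycine = 0.10,
                                        `c-di-GMP` = 0.10,
                                        Cobalamin = 0.05,
                                        Lysine = 0.05),
                      cogPool = c("COG0147", "COG0512", "COG0441",
                                  "COG0509", "COG0404", "COG0112",
                                  "COG0352", "COG1135", "COG0765",
                                  "COG9001", "COG9002", "COG9003"),
                      cogEnrichment = c(COG0147 = 4, COG0441 = 4),
                      terminatorPlantProb = 1,
                      tandemGapRange = c(30, 50),
                      adjacentGapRange = c(5, 15),
                      gcContent = 0.5, seed = 1) {
  new("SimConfig",
      nPhyla = as.integer(nPhyla),
      genomesPerPhylum = as.integer(genomesPerPhylum),
      genesPerGenome = as.integer(genesPerGenome),
      meanIntergenicLen = as.integer(meanIntergenicLen),
      baseRiboswitchRate = as.numeric(baseRiboswitchRate),
      phylumRateMultipliers = as.numeric(phylumRateMultipliers),
      architectureMix = architectureMix[names(.ARCH_ARITY)],
      familyWeights = familyWeights,
      cogPool = cogPool, cogEnrichment = cogEnrichment,
      terminatorPlantProb = as.numeric(terminatorPlantProb),
      tandemGapRange = as.integer(tandemGapRange),
      adjacentGapRange = as.integer(adjacentGapRange),
      gcContent = as.numeric(gcContent), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nPhyla, "phyla x", object@genomesPerPhylum,
      "genomes x", object@genesPerGenome, "genes; base rate",
      object@baseRiboswitchRate, "; seed", object@seed, "\n")
})

#' Splice the canonical terminator element into a sequence
#'
#' Overwrites 28 nt starting at `position` with an 8-bp G:C stem, 4-nt
#' loop and 8-nt T-tail; sequence length is preserved.  The element is
#' detected by [callTerminator()] under default parameters.
#'
#' @param sequence host nucleotide string.
#' @param position 1-based start of the splice.
#' @return the modified sequence.
#' @examples
#' plantTerminator(strrep("A", 60), 11)
#' @export
plantTerminator <- function(sequence, position) {
  w <- nchar(.TERM_ELEMENT)
  if (position < 1L || position + w - 1L > nchar(sequence))
    stopf("no room for a %d-nt terminator at position %d of a %d-nt sequence",
          w, position, nchar(sequence))
  paste0(substr(sequence, 1L, position - 1L), .TERM_ELEMENT,
         substr(sequence, position + w, nchar(sequence)))
}

# Background sequence: first-order Markov chain with the configured GC
# and mild same-base persistence (with probability 0.15 a position
# copies its predecessor, otherwise it is an independent draw from the
# GC-weighted base distribution), so shuffling and terminator
# false-positive behaviour see realistic short runs.  Vectorised via
# the last-independent-draw index.
.markovBackground <- function(len, gc) {
  if (len <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  x <- sample.int(4L, len, replace = TRUE, prob = p)
  keep <- c(TRUE, runif(len - 1L) >= 0.15)
  idx <- cummax(seq_len(len) * keep)
  paste(.DNA[x[idx]], collapse = "")
}

# Sample the planted content of one regulated gene's region.
.sampleArchitecture <- function(cfg) {
  arch <- sample(names(cfg@architectureMix), 1L,
                 prob = cfg@architectureMix)
  arity <- .ARCH_ARITY[[arch]]
  fams <- character(arity)
  fams[1] <- sample(names(cfg@familyWeights), 1L,
                    prob = cfg@familyWeights)
  if (arity > 1L) for (k in 2:arity)
    fams[k] <- if (runif(1) < 0.7) fams[k - 1L]
      else sample(names(cfg@familyWeights), 1L, prob = cfg@familyWeights)
  nJ <- arity - 1L
  gaps <- integer(0); planted <- logical(0)
  if (nJ > 0L) {
    rng <- if (.ARCH_CLASS[[arch]] == "adjacent") cfg@adjacentGapRange
      else cfg@tandemGapRange
    gaps <- sample(rng[1]:rng[2], nJ, replace = TRUE)
    planted <- .ARCH_CLASS[[arch]] == "tandem" &
      gaps >= nchar(.TERM_ELEMENT) &
      runif(nJ) < cfg@terminatorPlantProb
  }
  list(arch = arch, arity = arity, class = .ARCH_CLASS[[arch]],
       families = fams, gaps = gaps, planted = planted)
}

#' Simulate a genome collection with planted ground truth
#'
#' At `level = "counts"` only the tables the enrichment layer needs are
#' generated (gene table, aptamer analysis table, truth), which scales
#' to millions of genes.  At `level = "full"` every gene additionally
#' receives coordinates on a per-genome contig, regulated genes get an
#' upstream intergenic region with planted aptamer hits (emitted in
#' cmsearch tblout dialect, scores above a nominal 30-bit cutoff) and
#' canonical terminators at tandem junctions, and all files parse
#' cleanly through the package readers.  Regulated genes are laid out
#' on the plus strand with their planted region flanked by gene
#' bodies, so [extractIntergenic()] reproduces the planted regions
#' exactly; a fraction of unregulated genes is placed on the minus
#' strand.
#'
#' @param cfg a [SimConfig-class].
#' @param level `"full"` or `"counts"`.
#' @param nDecoys number of sub-threshold decoy hits (score 5-25 bits)
#'   planted on random regulated regions (full level only), to
#'   exercise [applyCutoffs()].
#' @return a list with elements `genes` (GRanges at full level, else
#'   data.frame), `aptamers` (analysis table of planted aptamers with
#'   their true `group_class`), `truth` (per-group data.frame:
#'   `region_id`, `genome_id`, `phylum`, `gene_id`, `arch`,
#'   `group_class`, `homogeneity`, `families`, `gaps`,
#'   `terminators_planted`), and at full level `contigs`
#'   (DNAStringSet), `regions` ([IntergenicRegionSet-class]), `hits`
#'   (GRanges), `config`.
#' @examples
#' sim <- simulateCollection(simConfig(nPhyla = 2, genomesPerPhylum = 1,
#'                                     genesPerGenome = 30, seed = 3))
#' table(sim$truth$group_class)
#' @export
simulateCollection <- function(cfg, level = c("full", "counts"),
                               nDecoys = 0L) {
  level <- match.arg(level)
  validObject(cfg)
  if (level == "counts")
    return(withSeed(cfg@seed, .simulateCounts(cfg)))
  withSeed(cfg@seed, .simulateFull(cfg, nDecoys))
}

.rateVector <- function(cfg) {
  mult <- cfg@phylumRateMultipliers
  if (length(mult) == 1L) mult <- rep(mult, cfg@nPhyla)
  mult
}

.simulateCounts <- function(cfg) {
  nPhy <- cfg@nPhyla
  perPhy <- cfg@genomesPerPhylum * cfg@genesPerGenome
  total <- nPhy * perPhy
  phyla <- sprintf("Phylum%02d", seq_len(nPhy))
  phy <- rep(phyla, each = perPhy)
  genome <- rep(sprintf("g%02d_%02d", rep(seq_len(nPhy),
                                          each = cfg@genomesPerPhylum),
                        rep(seq_len(cfg@genomesPerPhylum), nPhy)),
                each = cfg@genesPerGenome)
  gene <- paste0("gene", seq_len(total))
  cog <- sample(cfg@cogPool, total, replace = TRUE)
  mult <- rep(.rateVector(cfg), each = perPhy)
  cogMult <- rep(1, total)
  if (length(cfg@cogEnrichment)) {
    m <- match(cog, names(cfg@cogEnrichment))
    cogMult[!is.na(m)] <- cfg@cogEnrichment[m[!is.na(m)]]
  }
  rate <- pmin(1, cfg@baseRiboswitchRate * mult * cogMult)
  regulated <- stats::rbinom(total, 1L, rate) == 1L
  genes <- data.frame(gene_id = gene, genome_id = genome, phylum = phy,
                      cog_id = cog, species = genome,
                      regulated = regulated, stringsAsFactors = FALSE)
  idx <- which(regulated)
  nReg <- length(idx)
  arch <- sample(names(cfg@architectureMix), nReg, replace = TRUE,
                 prob = cfg@architectureMix)
  arity <- .ARCH_ARITY[arch]
  cls <- .ARCH_CLASS[arch]
  fam1 <- sample(names(cfg@familyWeights), nReg, replace = TRUE,
                 prob = cfg@familyWeights)
  aptRows <- rep(seq_len(nReg), arity)
  pos <- sequence(arity)  # 1..arity within each group
  fam <- fam1[aptRows]
  extra <- pos > 1L
  if (any(extra)) {
    redraw <- runif(sum(extra)) >= 0.7
    fam[extra][redraw] <- sample(names(cfg@familyWeights), sum(redraw),
                                 replace = TRUE,
                                 prob = cfg@familyWeights)
  }
  aptamers <- data.frame(
    hit_id = paste0("hit", seq_along(aptRows)),
    family = fam,
    genome_id = genome[idx][aptRows], gene_id = gene[idx][aptRows],
    phylum = phy[idx][aptRows], cog_id = cog[idx][aptRows],
    group_class = cls[aptRows], stringsAsFactors = FALSE)
  truth <- data.frame(
    region_id = paste0("igr|", genome[idx], "|", gene[idx]),
    genome_id = genome[idx], phylum = phy[idx], gene_id = gene[idx],
    arch = arch, group_class = unname(cls),
    homogeneity = NA_character_, families = NA_character_,
    gaps = "", terminators_planted = "", stringsAsFactors = FALSE)
  fams_by_group <- split(fam, aptRows)
  truth$families <- vapply(fams_by_group, paste, character(1),
                           collapse = ",")
  truth$homogeneity <- vapply(fams_by_group, function(f)
    if (length(f) < 2L) "n/a"
    else if (length(unique(f)) == 1L) "homogeneous"
    else "heterogeneous", character(1))
  list(genes = genes, aptamers = aptamers, truth = truth, config = cfg)
}

.simulateFull <- function(cfg, nDecoys) {
  nominalCutoff <- 30
  geneRows <- list(); regionRows <- list(); regionSeqList <- list()
  hitRows <- list(); truthRows <- list(); aptRows <- list()
  contigs <- list()
  mult <- .rateVector(cfg)
  for (pIdx in seq_len(cfg@nPhyla)) {
    phylum <- sprintf("Phylum%02d", pIdx)
    for (gIdx in seq_len(cfg@genomesPerPhylum)) {
      genome <- sprintf("g%02d_%02d", pIdx, gIdx)
      set.seed(deriveSeed(cfg@seed, pIdx, gIdx))
      contig <- paste0("ctg_", genome)
      cursor <- 0L
      segs <- character(0)
      for (k in seq_len(cfg@genesPerGenome)) {
        geneId <- sprintf("%s_g%04d", genome, k)
        cog <- sample(cfg@cogPool, 1L)
        cm <- if (cog %in% names(cfg@cogEnrichment))
          cfg@cogEnrichment[[cog]] else 1
        regulated <- runif(1) < min(1, cfg@baseRiboswitchRate *
                                      mult[pIdx] * cm)
        geneLen <- sample(300:900, 1L)
        if (!regulated && runif(1) < 0.3) {
          # minus-strand unregulated gene: gene body only
          segs <- c(segs, .markovBackground(geneLen, cfg@gcContent))
          geneRows[[length(geneRows) + 1L]] <- data.frame(
            genome_id = genome, species = genome, phylum = phylum,
            contig = contig, start = cursor + 1L,
            end = cursor + geneLen, strand = "-", gene_id = geneId,
            cog_id = cog, stringsAsFactors = FALSE)
          cursor <- cursor + geneLen
          next
        }
        if (!regulated) {
          igrLen <- sample(max(10L, as.integer(cfg@meanIntergenicLen / 2)):
                             as.integer(cfg@meanIntergenicLen * 1.5), 1L)
          segs <- c(segs, .markovBackground(igrLen, cfg@gcContent),
                    .markovBackground(geneLen, cfg@gcContent))
          geneRows[[length(geneRows) + 1L]] <- data.frame(
            genome_id = genome, species = genome, phylum = phylum,
            contig = contig, start = cursor + igrLen + 1L,
            end = cursor + igrLen + geneLen, strand = "+",
            gene_id = geneId, cog_id = cog, stringsAsFactors = FALSE)
          cursor <- cursor + igrLen + geneLen
          next
        }
        # regulated gene: planted region
        plan <- .sampleArchitecture(cfg)
        aptLens <- sample(60:120, plan$arity, replace = TRUE)
        lead <- sample(10:30, 1L)
        tail_ <- sample(60:80, 1L)
        igrLen <- lead + sum(aptLens) + sum(plan$gaps) + tail_
        igrSeq <- .markovBackground(igrLen, cfg@gcContent)
        aptStart <- integer(plan$arity); aptEnd <- integer(plan$arity)
        at <- lead + 1L
        for (a in seq_len(plan$arity)) {
          aptStart[a] <- at; aptEnd[a] <- at + aptLens[a] - 1L
          at <- aptEnd[a] + 1L
          if (a < plan$arity) {
            if (plan$planted[a])
              igrSeq <- plantTerminator(igrSeq, at)
            at <- at + plan$gaps[a]
          }
        }
        regionId <- paste0("igr|", genome, "|", geneId)
        segs <- c(segs, igrSeq,
                  .markovBackground(geneLen, cfg@gcContent))
        regionRows[[length(regionRows) + 1L]] <- data.frame(
          contig = contig, start = cursor + 1L, end = cursor + igrLen,
          region_id = regionId, genome_id = genome,
          downstream_gene_id = geneId, stringsAsFactors = FALSE)
        regionSeqList[[regionId]] <- igrSeq
        geneRows[[length(geneRows) + 1L]] <- data.frame(
          genome_id = genome, species = genome, phylum = phylum,
          contig = contig, start = cursor + igrLen + 1L,
          end = cursor + igrLen + geneLen, strand = "+",
          gene_id = geneId, cog_id = cog, stringsAsFactors = FALSE)
        hitRows[[length(hitRows) + 1L]] <- data.frame(
          region_ref = regionId,
          start = aptStart, end = aptEnd,
          model_class = plan$families,
          bit_score = round(runif(plan$arity, nominalCutoff + 5,
                                  nominalCutoff + 60), 1),
          stringsAsFactors = FALSE)
        aptRows[[length(aptRows) + 1L]] <- data.frame(
          family = plan$families, genome_id = genome, gene_id = geneId,
          phylum = phylum, cog_id = cog, group_class = plan$class,
          stringsAsFactors = FALSE)
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          region_id = regionId, genome_id = genome, phylum = phylum,
          gene_id = geneId, arch = plan$arch, group_class = plan$class,
          homogeneity = if (plan$arity < 2L) "n/a"
            else if (length(unique(plan$families)) == 1L) "homogeneous"
            else "heterogeneous",
          families = paste(plan$families, collapse = ","),
          gaps = paste(plan$gaps, collapse = ","),
          terminators_planted = paste(plan$planted, collapse = ","),
          stringsAsFactors = FALSE)
        cursor <- cursor + igrLen + geneLen
      }
      contigs[[contig]] <- paste(segs, collapse = "")
    }
  }
  genesDf <- do.call(rbind, geneRows)
  genes <- GenomicRanges::GRanges(
    seqnames = genesDf$contig,
    ranges = IRanges::IRanges(genesDf$start, genesDf$end),
    strand = genesDf$strand,
    genome_id = genesDf$genome_id, species = genesDf$species,
    phylum = genesDf$phylum, gene_id = genesDf$gene_id,
    cog_id = genesDf$cog_id)
  regDf <- do.call(rbind, regionRows)
  regions <- if (is.null(regDf)) .emptyRegionSet() else {
    gr <- GenomicRanges::GRanges(
      seqnames = regDf$contig,
      ranges = IRanges::IRanges(regDf$start, regDf$end),
      strand = "+", region_id = regDf$region_id,
      genome_id = regDf$genome_id,
      downstream_gene_id = regDf$downstream_gene_id)
    sq <- Biostrings::DNAStringSet(unlist(regionSeqList[regDf$region_id]))
    names(sq) <- regDf$region_id
    new("IntergenicRegionSet", ranges = gr, seq = sq)
  }
  hitDf <- do.call(rbind, hitRows)
  hits <- if (is.null(hitDf)) .emptyHitGr() else {
    fam <- riboswitchFamilyMap()
    # planted model class: use a concrete member class of the family
    classOf <- vapply(hitDf$model_class, function(f) {
      members <- names(fam)[fam == f]
      if (length(members)) members[1] else f
    }, character(1))
    GenomicRanges::GRanges(
      seqnames = hitDf$region_ref,
      ranges = IRanges::IRanges(hitDf$start, hitDf$end), strand = "+",
      hit_id = paste0(hitDf$region_ref, ":", hitDf$start, "-",
                      hitDf$end, ":", classOf),
      model_class = classOf, model_acc = "-",
      bit_score = hitDf$bit_score,
      evalue = 10^-(hitDf$bit_score / 4),
      region_ref = hitDf$region_ref)
  }
  if (nDecoys > 0L && length(hits)) {
    pick <- sample(seq_along(hits), min(nDecoys, length(hits)))
    dec <- hits[pick]
    dec$bit_score <- round(runif(length(dec), 5, 25), 1)
    dec$evalue <- 10^-(dec$bit_score / 4)
    dec$hit_id <- paste0(dec$hit_id, ":decoy")
    hits <- c(hits, dec)
  }
  apt <- do.call(rbind, aptRows)
  if (!is.null(apt)) apt$hit_id <- paste0("hit", seq_len(nrow(apt)))
  list(genes = genes,
       contigs = Biostrings::DNAStringSet(unlist(contigs)),
       regions = regions, hits = hits,
       aptamers = apt,
       truth = do.call(rbind, truthRows),
       config = cfg)
}

#' Write a simulated collection to disk
#'
#' Emits `genes.tsv` (package TSV dialect), `contigs.fasta`,
#' `regions.fasta`, `hits.tbl` (tblout dialect) and `truth.json`, all
#' of which round-trip through the package readers.
#'
#' @param sim result of [simulateCollection()] at level `"full"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCollection <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeGeneTable(sim$genes, file.path(dir, "genes.tsv"))
  Biostrings::writeXStringSet(sim$contigs,
                              file.path(dir, "contigs.fasta"))
  writeRegionsFasta(sim$regions, file.path(dir, "regions.fasta"))
  writeTblout(sim$hits, file.path(dir, "hits.tbl"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows")
  invisible(dir)
}
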