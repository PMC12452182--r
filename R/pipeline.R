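# End-to-end composition of the analysis stages: read inputs, filter
# hits, group, scan terminators, classify, run enrichments, write
# results with a run manifest.

#' Run the full contiguous-riboswitch pipeline
#'
#' Stages, in order: read the gene table, region FASTA, hit table and
#' family map; optionally filter hits through empirical bit-score
#' cutoffs; deduplicate overlapping hits; group hits by intergenic
#' region; scan inter-aptamer junctions for intrinsic terminators;
#' classify architectures and homogeneity; run the requested
#' enrichment analyses.  Results (`groups.tsv`, `terminators.tsv`,
#' `enrichment.tsv`) and a run manifest (`manifest.json` with
#' parameter values, input digests and package version) are written to
#' `outDir`.  Outputs are pure functions of the inputs and parameters.
#'
#' Region sequence names must be region ids of the form
#' `igr|<genome_id>|<gene_id>` (as produced by [extractIntergenic()]
#' and [writeRegionsFasta()]), which ties every hit back to its
#' regulated gene.
#'
#' @param genesFile gene table path (TSV dialect).
#' @param regionsFasta intergenic region FASTA path.
#' @param hitsFile cmsearch tblout path.
#' @param outDir output directory.
#' @param familyMapFile optional TSV; defaults to the packaged map.
#' @param cutoffs optional data.frame or named vector for
#'   [applyCutoffs()].
#' @param analyses analysis ids for [runEnrichment()].
#' @param termParams,archP parameter objects.
#' @return invisibly, a list with the classified
#'   [ContiguousGroupSet-class], the terminator calls, the enrichment
#'   table and the manifest.
#' @export
runPipeline <- function(genesFile, regionsFasta, hitsFile, outDir,
                        familyMapFile = NULL, cutoffs = NULL,
                        analyses = c("S6", "S7", "S9", "S10"),
                        termParams = terminatorParams(),
                        archP = archParams()) {
  for (f in c(genesFile, regionsFasta, hitsFile, familyMapFile))
    if (!is.null(f) && !file.exists(f))
      stopf("pipeline input missing: %s", f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  genes <- stage("read_genes", readGeneTable(genesFile))
  fam <- stage("family_map",
               if (is.null(familyMapFile)) riboswitchFamilyMap()
               else readFamilyMap(familyMapFile))
  seqs <- stage("read_regions",
                Biostrings::readDNAStringSet(regionsFasta))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  regions <- stage("regions", .regionsFromFasta(seqs, genes))
  hits <- stage("read_hits", readTblout(hitsFile))
  if (!is.null(cutoffs))
    hits <- stage("apply_cutoffs", applyCutoffs(hits, cutoffs))
  hits <- stage("assign_families", assignFamilies(hits, fam))
  hits <- stage("dedupe", dedupeHits(hits, archP))
  groups <- stage("group", groupContiguous(hits, regions))
  terms <- stage("terminators",
                 scanInterAptamer(groups, regions, termParams))
  groups <- stage("classify",
                  labelHomogeneity(classifyGroups(groups, terms, archP),
                                   fam))
  aptTab <- stage("analysis_table", buildAnalysisTable(genes, groups))
  enr <- stage("enrichment",
               runEnrichment(analyses, genes, aptTab, bh = TRUE))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(groupTable(groups),
                     file.path(outDir, "groups.tsv"), sep = "\t")
  data.table::fwrite(terms, file.path(outDir, "terminators.tsv"),
                     sep = "\t")
  data.table::fwrite(enr, file.path(outDir, "enrichment.tsv"),
                     sep = "\t")
  manifest <- list(
    package = "riboArch",
    version = as.character(utils::packageVersion("riboArch")),
    inputs = list(
      genes = unname(tools::md5sum(genesFile)),
      regions = unname(tools::md5sum(regionsFasta)),
      hits = unname(tools::md5sum(hitsFile))),
    params = list(
      windowLen = termParams@windowLen, tRunMinT = termParams@tRunMinT,
      tRunWindow = termParams@tRunWindow,
      dgThreshold = termParams@dgThreshold, maxGap = termParams@maxGap,
      adjacencyThreshold = archP@adjacencyThreshold,
      overlapFrac = archP@overlapFrac),
    analyses = analyses)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(groups = groups, terminators = terms,
                 enrichment = enr, manifest = manifest))
}

# Rebuild an IntergenicRegionSet from a region FASTA whose names follow
# the igr|genome|gene convention; coordinates are region-local (the
# genomic placement is not recoverable from FASTA and is not needed
# downstream of extraction).
.regionsFromFasta <- function(seqs, genes) {
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stopf("region name '%s' does not follow igr|genome|gene", ids[bad][1])
  genome <- vapply(parts, `[[`, character(1), 2L)
  gene <- vapply(parts, `[[`, character(1), 3L)
  gr <- GenomicRanges::GRanges(
    seqnames = ids,
    ranges = IRanges::IRanges(1L, BiocGenerics::width(seqs)),
    strand = "+", region_id = ids, genome_id = genome,
    downstream_gene_id = gene)
  new("IntergenicRegionSet", ranges = gr, seq = seqs)
}
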