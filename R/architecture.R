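# Grouping aptamer hits into contiguous sets and classifying their
# architecture (tandemly arranged riboswitches vs adjacent aptamers)
# and ligand homogeneity.

#' Remove redundant overlapping hits
#'
#' Covariance models of related classes often match the same locus;
#' counting such matches as contiguous pairs would be wrong.  Among
#' hits on the same region whose intervals overlap by more than
#' `overlapFrac` of the shorter one, only the best survives: highest
#' bit score, ties by lower E-value, then lexicographic model name.
#' Selection is greedy from the best hit down, so a chain a-b-c where
#' only consecutive hits overlap keeps both a and c.
#'
#' @param hits a hit `GRanges` (see [readTblout()]).
#' @param params an [ArchParams-class].
#' @return the filtered `GRanges`.
#' @export
dedupeHits <- function(hits, params = archParams()) {
  if (length(hits) < 2L) return(hits)
  o <- order(-hits$bit_score, hits$evalue, hits$model_class)
  hits <- hits[o]
  keep <- logical(length(hits))
  for (idx in seq_along(hits)) {
    if (any(keep)) {
      prev <- which(keep &
                      hits$region_ref == hits$region_ref[idx])
      if (length(prev)) {
        ov <- pmin(GenomicRanges::end(hits)[prev],
                   GenomicRanges::end(hits)[idx]) -
          pmax(GenomicRanges::start(hits)[prev],
               GenomicRanges::start(hits)[idx]) + 1L
        shorter <- pmin(GenomicRanges::width(hits)[prev],
                        GenomicRanges::width(hits)[idx])
        if (any(ov > params@overlapFrac * shorter)) next
      }
    }
    keep[idx] <- TRUE
  }
  hits <- hits[keep]
  hits[order(hits$region_ref, GenomicRanges::start(hits))]
}

#' Group aptamer hits sharing an intergenic region
#'
#' A set of riboswitches is contiguous when the aptamers lie in a
#' common intergenic region and hence regulate the same downstream gene
#' (or operon).  One group is built per region holding at least one
#' hit; aptamers are ordered 5' to 3' in transcript orientation and
#' junction gaps are the unpaired nt between consecutive aptamers.
#'
#' @param hits a deduplicated hit `GRanges` with `family` column (see
#'   [dedupeHits()], [assignFamilies()]).
#' @param regions the [IntergenicRegionSet-class] the hits refer to
#'   (supplies the regulated gene and genome); may be `NULL` when hits
#'   carry no region context beyond the id.
#' @return a [ContiguousGroupSet-class]; `group_class` is `"single"`
#'   for one-aptamer groups and `"unclassified"` until
#'   [classifyGroups()] is applied.
#' @export
groupContiguous <- function(hits, regions = NULL) {
  if (is.null(hits$family)) hits <- assignFamilies(hits)
  regs <- unique(as.character(hits$region_ref))
  geneOf <- genomeOf <- setNames(rep(NA_character_, length(regs)), regs)
  if (!is.null(regions)) {
    m <- match(regs, regionIds(regions))
    geneOf[] <- as.character(regionRanges(regions)$downstream_gene_id)[m]
    genomeOf[] <- as.character(regionRanges(regions)$genome_id)[m]
  }
  rows <- vector("list", length(regs))
  aptList <- vector("list", length(regs))
  for (gidx in seq_along(regs)) {
    members <- hits[hits$region_ref == regs[gidx]]
    members <- members[order(GenomicRanges::start(members),
                             GenomicRanges::end(members))]
    n <- length(members)
    gaps <- if (n > 1L)
      GenomicRanges::start(members)[-1L] -
        GenomicRanges::end(members)[-n] - 1L
    else integer(0)
    if (any(gaps < 0L))
      stopf("region %s: overlapping aptamers after deduplication (gap %d)",
            regs[gidx], min(gaps))
    fams <- as.character(members$family)
    members$group <- gidx
    aptList[[gidx]] <- members
    rows[[gidx]] <- S4Vectors::DataFrame(
      region_ref = regs[gidx],
      genome_id = genomeOf[[gidx]],
      regulated_gene_ids = I(list(geneOf[[gidx]])),
      n_aptamers = n,
      junction_gaps = I(list(gaps)),
      junction_classes = I(list(rep(NA_character_, length(gaps)))),
      terminator_evidence = I(list(rep(NA, length(gaps)))),
      group_class = if (n == 1L) "single" else "unclassified",
      homogeneity = if (n == 1L) "n/a"
        else if (length(unique(fams)) == 1L) "homogeneous"
        else "heterogeneous",
      architecture_string = paste(fams, collapse = " "))
  }
  groups <- do.call(rbind, rows)
  new("ContiguousGroupSet", groups = groups,
      aptamers = do.call(c, unname(aptList)))
}

#' Classify contiguous groups as tandem or adjacent architectures
#'
#' Every junction with an inter-aptamer gap strictly below the
#' adjacency threshold is labelled `adjacent` (two sensor domains too
#' close to host an expression platform between them), all other
#' junctions `tandem`.  The group class is the common junction label,
#' `mixed` when junctions disagree, `single` for lone aptamers.
#' Terminator calls are recorded as per-junction supporting evidence
#' for tandem arrangements; the distance rule stays authoritative.
#'
#' @param groups a [ContiguousGroupSet-class].
#' @param terminators optional data.frame from [scanInterAptamer()].
#' @param params an [ArchParams-class].
#' @return the updated `ContiguousGroupSet`.
#' @export
classifyGroups <- function(groups, terminators = NULL,
                           params = archParams()) {
  g <- groups@groups
  thr <- params@adjacencyThreshold
  for (gidx in seq_len(nrow(g))) {
    gaps <- g$junction_gaps[[gidx]]
    if (!length(gaps)) next
    jc <- ifelse(gaps < thr, "adjacent", "tandem")
    ev <- rep(FALSE, length(gaps))
    if (!is.null(terminators) && nrow(terminators)) {
      hit <- terminators$region_ref == g$region_ref[gidx]
      ev[terminators$junction[hit]] <- TRUE
    }
    g$junction_classes[[gidx]] <- jc
    g$terminator_evidence[[gidx]] <- ev
    g$group_class[gidx] <- if (length(unique(jc)) == 1L) jc[1] else "mixed"
  }
  groups@groups <- g
  validObject(groups)
  groups
}

#' Relabel ligand homogeneity under a family map
#'
#' Reassigns each member aptamer's family from its covariance-model
#' class via `familyMap`, then recomputes the homogeneity label
#' (`homogeneous` when all aptamers sense the same ligand family,
#' `heterogeneous` otherwise, `n/a` for single aptamers) and the
#' 5'-to-3' architecture string.
#'
#' @param groups a [ContiguousGroupSet-class].
#' @param familyMap named character vector (see [readFamilyMap()]).
#' @return the updated `ContiguousGroupSet`.
#' @export
labelHomogeneity <- function(groups, familyMap = riboswitchFamilyMap()) {
  apt <- assignFamilies(groups@aptamers, familyMap)
  g <- groups@groups
  for (gidx in seq_len(nrow(g))) {
    fams <- as.character(apt$family[apt$group == gidx])
    g$architecture_string[gidx] <- paste(fams, collapse = " ")
    g$homogeneity[gidx] <- if (length(fams) < 2L) "n/a"
      else if (length(unique(fams)) == 1L) "homogeneous"
      else "heterogeneous"
  }
  groups@groups <- g
  groups@aptamers <- apt
  validObject(groups)
  groups
}

#' Flat summary table of contiguous groups
#'
#' @param groups a [ContiguousGroupSet-class].
#' @return a data.frame with one row per group: region, regulated gene,
#'   aptamer count, architecture string, group class, homogeneity,
#'   comma-separated junction gaps / classes / terminator evidence.
#' @export
groupTable <- function(groups) {
  g <- groups@groups
  data.frame(
    region_ref = as.character(g$region_ref),
    genome_id = as.character(g$genome_id),
    regulated_gene = vapply(g$regulated_gene_ids, function(x)
      paste(x, collapse = ","), character(1)),
    n_aptamers = g$n_aptamers,
    architecture_string = g$architecture_string,
    group_class = g$group_class,
    homogeneity = g$homogeneity,
    junction_gaps = vapply(g$junction_gaps, function(x)
      paste(x, collapse = ","), character(1)),
    junction_classes = vapply(g$junction_classes, function(x)
      paste(x, collapse = ","), character(1)),
    terminator_evidence = vapply(g$terminator_evidence, function(x)
      paste(x, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' @describeIn ContiguousGroupSet-class number of groups
#' @param x a `ContiguousGroupSet`.
#' @export
setMethod("length", "ContiguousGroupSet", function(x) nrow(x@groups))

#' Member aptamer hits of a group set
#' @param groups a [ContiguousGroupSet-class].
#' @return a `GRanges` with a `group` index column.
#' @export
groupAptamers <- function(groups) groups@aptamers

setMethod("show", "ContiguousGroupSet", function(object) {
  g <- object@groups
  cat("ContiguousGroupSet:", nrow(g), "groups,",
      sum(g$n_aptamers), "aptamers\n")
  if (nrow(g)) {
    tab <- table(g$group_class)
    cat("classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
})
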