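# Strand-aware upstream intergenic region extraction.

#' Extract the upstream intergenic region of every gene
#'
#' For each gene, the gap immediately upstream in its transcription
#' direction is extracted: for a `+` gene the span between the nearest
#' annotated gene end (any strand) and the gene start, for a `-` gene
#' the span between the gene end and the nearest annotated gene start.
#' Gaps of length zero yield no region.  Regions are bounded by gene
#' bodies, so they never overlap an annotated gene of the same genome;
#' two divergently transcribed neighbours each receive their own
#' (possibly coinciding) upstream region.  Minus-strand sequences are
#' stored reverse-complemented so that position increases toward the
#' downstream gene's start codon.
#'
#' @param genes a gene `GRanges` for a single genome or several (see
#'   [readGeneTable()]); contig names must be unique across genomes.
#' @param contigSeqs a named [Biostrings::DNAStringSet] of contig
#'   sequences.
#' @return an [IntergenicRegionSet-class].
#' @examples
#' library(GenomicRanges)
#' library(Biostrings)
#' genes <- GRanges("c1", IRanges(c(21, 61), c(40, 80)), strand = "+",
#'                  genome_id = "g", species = "s", phylum = "p",
#'                  gene_id = c("a", "b"), cog_id = NA_character_)
#' ctg <- DNAStringSet(c(c1 = paste(rep("ACGT", 25), collapse = "")))
#' extractIntergenic(genes, ctg)
#' @export
extractIntergenic <- function(genes, contigSeqs) {
  if (!length(genes)) return(.emptyRegionSet())
  contigs <- as.character(GenomicRanges::seqnames(genes))
  missing <- setdiff(unique(contigs), names(contigSeqs))
  if (length(missing))
    stopf("contigs absent from sequence set: %s",
          paste(missing, collapse = ", "))
  ctgLen <- setNames(BiocGenerics::width(contigSeqs), names(contigSeqs))
  if (any(GenomicRanges::end(genes) > ctgLen[contigs]))
    stopf("gene '%s' extends past the end of contig '%s'",
          genes$gene_id[which(GenomicRanges::end(genes) >
                                ctgLen[contigs])[1]],
          contigs[which(GenomicRanges::end(genes) > ctgLen[contigs])[1]])

  res <- vector("list", length(unique(contigs)))
  names(res) <- unique(contigs)
  for (ctg in unique(contigs)) {
    g <- genes[contigs == ctg]
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
    str <- as.character(GenomicRanges::strand(g))
    # free spans between occupied gene bodies on this contig
    occ <- IRanges::reduce(IRanges::IRanges(s, e))
    free <- IRanges::gaps(occ, start = 1L, end = ctgLen[[ctg]])
    fs <- IRanges::start(free); fe <- IRanges::end(free)
    rs <- ri <- integer(0); gi <- integer(0)
    for (k in seq_along(g)) {
      if (str[k] == "+") {
        # the free span ending flush against the gene start, if any
        hit <- which(fe == s[k] - 1L)
      } else {
        hit <- which(fs == e[k] + 1L)
      }
      if (length(hit) == 1L) {
        rs <- c(rs, fs[hit]); ri <- c(ri, fe[hit]); gi <- c(gi, k)
      }
    }
    if (!length(gi)) next
    gr <- GenomicRanges::GRanges(
      seqnames = ctg, ranges = IRanges::IRanges(rs, ri),
      strand = str[gi],
      region_id = paste0("igr|", g$genome_id[gi], "|", g$gene_id[gi]),
      genome_id = g$genome_id[gi],
      downstream_gene_id = g$gene_id[gi])
    res[[ctg]] <- gr
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(.emptyRegionSet())
  # per-contig pieces carry disjoint seqlevels; combining them is fine
  gr <- suppressWarnings(do.call(c, unname(res)))
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(k) {
    ctg <- as.character(GenomicRanges::seqnames(gr))[k]
    sq <- as.character(Biostrings::subseq(
      contigSeqs[[ctg]], GenomicRanges::start(gr)[k],
      GenomicRanges::end(gr)[k]))
    if (as.character(GenomicRanges::strand(gr))[k] == "-") revComp(sq) else sq
  }, character(1)))
  names(seqs) <- gr$region_id
  new("IntergenicRegionSet", ranges = gr, seq = seqs)
}

.emptyRegionSet <- function() {
  gr <- GenomicRanges::GRanges(region_id = character(),
                               genome_id = character(),
                               downstream_gene_id = character())
  new("IntergenicRegionSet", ranges = gr,
      seq = Biostrings::DNAStringSet())
}

#' @describeIn IntergenicRegionSet-class number of regions
#' @param x an `IntergenicRegionSet`.
#' @export
setMethod("length", "IntergenicRegionSet", function(x) length(x@ranges))

#' Accessors for IntergenicRegionSet
#'
#' `regionSeqs()` returns the transcript-oriented sequences,
#' `regionRanges()` the genomic ranges, `regionIds()` the identifiers.
#'
#' @param x an [IntergenicRegionSet-class].
#' @return a `DNAStringSet`, `GRanges` or `character` respectively.
#' @name region-accessors
NULL

#' @rdname region-accessors
#' @export
regionSeqs <- function(x) x@seq

#' @rdname region-accessors
#' @export
regionRanges <- function(x) x@ranges

#' @rdname region-accessors
#' @export
regionIds <- function(x) as.character(x@ranges$region_id)

setMethod("show", "IntergenicRegionSet", function(object) {
  cat("IntergenicRegionSet with", length(object), "regions;",
      "total", sum(BiocGenerics::width(object@seq)), "nt\n")
  if (length(object)) {
    cat("genomes:",
        paste(head(unique(object@ranges$genome_id), 5), collapse = ", "))
    if (length(unique(object@ranges$genome_id)) > 5) cat(", ...")
    cat("\n")
  }
})

#' Subset an IntergenicRegionSet
#' @param x an `IntergenicRegionSet`.
#' @param i logical, integer or character (region id) index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "IntergenicRegionSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, regionIds(x))
  new("IntergenicRegionSet", ranges = x@ranges[i], seq = x@seq[i])
})

#' Write intergenic region sequences as FASTA
#'
#' Sequence names are the region ids, so covariance-model hit tables
#' produced against this FASTA refer back to regions directly.
#'
#' @param regions an [IntergenicRegionSet-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeRegionsFasta <- function(regions, path) {
  Biostrings::writeXStringSet(regionSeqs(regions), path)
  invisible(path)
}
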