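# Gene annotation I/O.  The in-memory representation of a gene table is
# a GRanges (seqnames = contig, 1-based inclusive coordinates, strand)
# with metadata columns genome_id, species, phylum, gene_id, cog_id
# (cog_id may be NA).  The package's TSV dialect on disk uses 0-based
# half-open coordinates; GFF3 is 1-based inclusive.  Conversions happen
# only here, at the I/O boundary.

.geneTsvCols <- c("genome_id", "species", "phylum", "contig",
                  "start", "end", "strand", "gene_id", "cog_id")

.validateGeneGr <- function(gr, where) {
  if (any(BiocGenerics::width(gr) < 1L))
    stopf("%s: gene with end <= start after coordinate conversion", where)
  if (!all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
    stopf("%s: strand must be '+' or '-' for every gene", where)
  key <- paste(gr$genome_id, gr$gene_id)
  if (anyDuplicated(key))
    stopf("%s: duplicated (genome_id, gene_id): %s", where,
          key[duplicated(key)][1])
  gr
}

.sortGeneGr <- function(gr) {
  o <- order(gr$genome_id, as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  gr[o]
}

#' Read a gene annotation table
#'
#' Reads gene annotations either from the package's TSV dialect (header
#' `genome_id species phylum contig start end strand gene_id cog_id`,
#' coordinates 0-based half-open) or from GFF3 (1-based inclusive;
#' attributes `ID`, `genome_id`, `species`, `phylum`, `cog_id`).  Both
#' are converted to the internal 1-based inclusive `GRanges`
#' representation and sorted by (genome, contig, start).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @return a `GRanges` with mcols `genome_id`, `species`, `phylum`,
#'   `gene_id`, `cog_id`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   paste(c("genome_id","species","phylum","contig","start","end",
#'           "strand","gene_id","cog_id"), collapse = "\t"),
#'   "gA\tsp1\tBacillota\tc1\t10\t20\t+\tg1\tCOG0147"), tf)
#' readGeneTable(tf)
#' @seealso [writeGeneTable()], [selectRepresentatives()]
#' @export
readGeneTable <- function(path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("gene table not found: %s", path)
  gr <- switch(dialect,
               tsv = .readGeneTsv(path),
               gff3 = .readGeneGff3(path))
  .sortGeneGr(.validateGeneGr(gr, path))
}

.readGeneTsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.emptyGeneGr())
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, .geneTsvCols))
    stopf("%s line 1: expected header '%s'", path,
          paste(.geneTsvCols, collapse = " "))
  if (length(lines) == 1L) return(.emptyGeneGr())
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  # a trailing empty cog_id field is dropped by strsplit; restore it
  fields <- lapply(fields, function(f)
    if (length(f) == length(.geneTsvCols) - 1L) c(f, "") else f)
  bad <- which(lengths(fields) != length(.geneTsvCols))
  if (length(bad))
    stopf("%s line %d: expected %d tab-separated fields, got %d",
          path, bad[1] + 1L, length(.geneTsvCols),
          lengths(fields)[bad[1]])
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.numeric(m[, 5]))
  end0 <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stopf("%s line %d: non-numeric coordinate", path, bad[1] + 1L)
  cog <- m[, 9]
  cog[cog %in% c("", "NA", ".")] <- NA_character_
  GenomicRanges::GRanges(
    seqnames = m[, 4],
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = m[, 7],
    genome_id = m[, 1], species = m[, 2], phylum = m[, 3],
    gene_id = m[, 8], cog_id = cog)
}

.readGeneGff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stopf("malformed GFF3 in %s: %s", path, conditionMessage(e)))
  if (!length(gr)) return(.emptyGeneGr())
  gr <- gr[gr$type %in% "gene"]
  mc <- S4Vectors::mcols(gr)
  getAttr <- function(nm, default = NA_character_) {
    if (nm %in% colnames(mc)) as.character(mc[[nm]])
    else rep(default, length(gr))
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    genome_id = getAttr("genome_id"), species = getAttr("species"),
    phylum = getAttr("phylum"), gene_id = getAttr("ID"),
    cog_id = getAttr("cog_id"))
  if (anyNA(out$gene_id)) stopf("%s: GFF3 gene without ID attribute", path)
  out
}

.emptyGeneGr <- function() {
  GenomicRanges::GRanges(
    genome_id = character(), species = character(), phylum = character(),
    gene_id = character(), cog_id = character())
}

#' Write a gene table in the package TSV dialect
#'
#' Inverse of [readGeneTable()] for the TSV dialect (0-based half-open
#' on disk); `readGeneTable(writeGeneTable(gr, f))` reproduces `gr` up
#' to sorting.
#'
#' @param genes a gene `GRanges` as returned by [readGeneTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  cog <- genes$cog_id
  cog[is.na(cog)] <- ""
  dt <- data.table::data.table(
    genome_id = genes$genome_id, species = genes$species,
    phylum = genes$phylum,
    contig = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    gene_id = genes$gene_id, cog_id = cog)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Keep one representative genome per species
#'
#' For every species the genome with the largest gene count is retained;
#' ties are broken by the lexicographically smallest `genome_id` so the
#' selection is deterministic.  Applying the selection twice changes
#' nothing.
#'
#' @param genes a gene `GRanges` (see [readGeneTable()]).
#' @return the subset of `genes` belonging to representative genomes.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   paste(c("genome_id","species","phylum","contig","start","end",
#'           "strand","gene_id","cog_id"), collapse = "\t"),
#'   "gA\tsp1\tBacillota\tc1\t0\t10\t+\tg1\t",
#'   "gA\tsp1\tBacillota\tc1\t20\t30\t+\tg2\t",
#'   "gB\tsp1\tBacillota\tc1\t0\t10\t+\tg1\t"), tf)
#' g <- readGeneTable(tf)
#' unique(selectRepresentatives(g)$genome_id)  # "gA": 2 genes beats 1
#' @export
selectRepresentatives <- function(genes) {
  if (!length(genes)) return(genes)
  dt <- data.table::data.table(species = genes$species,
                               genome_id = genes$genome_id)
  counts <- dt[, .N, by = .(species, genome_id)]
  data.table::setorder(counts, species, -N, genome_id)
  keep <- counts[, .SD[1], by = species]$genome_id
  genes[genes$genome_id %in% keep]
}
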