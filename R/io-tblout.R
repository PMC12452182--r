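# Infernal cmsearch tabular output (--tblout, format 1).  Columns are
# whitespace-separated: target name, target accession, query name,
# query accession, mdl, mdl from, mdl to, seq from, seq to, strand,
# trunc, pass, gc, bias, score, E-value, inc, description.  seq-from /
# seq-to are 1-based inclusive and swapped on the minus strand.

#' Read an Infernal cmsearch tblout hit table
#'
#' Hits are returned as a `GRanges` on the named targets (here:
#' intergenic region ids), coordinates normalised to the plus strand of
#' the target (1-based inclusive, `start <= end`), with the original
#' strand recorded and bit score / E-value kept as numbers.
#'
#' @param path tblout file path.
#' @return a `GRanges` with mcols `hit_id`, `model_class`, `model_acc`,
#'   `bit_score`, `evalue`, `region_ref`.
#' @examples
#' tf <- tempfile(fileext = ".tbl")
#' writeLines(c("# comment",
#'   paste("igr1 - SAM RF00162 cm 1 100 5 104 + no 1 0.5 0.0",
#'         "42.5 1e-08 ! -")), tf)
#' readTblout(tf)
#' @seealso [writeTblout()], [applyCutoffs()]
#' @export
readTblout <- function(path) {
  if (!file.exists(path)) stopf("tblout file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(.emptyHitGr())
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 17L)
  if (length(bad))
    stopf("%s line %d: expected >= 17 whitespace-separated columns",
          path, lineNo[bad[1]])
  m <- t(vapply(fields, function(f) f[1:17], character(17)))
  from <- suppressWarnings(as.numeric(m[, 8]))
  to <- suppressWarnings(as.numeric(m[, 9]))
  score <- suppressWarnings(as.numeric(m[, 15]))
  ev <- suppressWarnings(as.numeric(m[, 16]))
  for (col in list(c("seq-from", 8), c("seq-to", 9),
                   c("score", 15), c("E-value", 16))) {
    v <- suppressWarnings(as.numeric(m[, as.integer(col[2])]))
    if (anyNA(v))
      stopf("%s line %d: non-numeric %s field", path,
            lineNo[which(is.na(v))[1]], col[1])
  }
  strand <- m[, 10]
  if (!all(strand %in% c("+", "-")))
    stopf("%s line %d: bad strand field", path,
          lineNo[which(!strand %in% c("+", "-"))[1]])
  start <- ifelse(strand == "+", from, to)
  end <- ifelse(strand == "+", to, from)
  if (any(start > end))
    stopf("%s line %d: inverted coordinates for declared strand",
          path, lineNo[which(start > end)[1]])
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1], ranges = IRanges::IRanges(start, end),
    strand = strand,
    hit_id = paste0(m[, 1], ":", start, "-", end, ":", m[, 3]),
    model_class = m[, 3], model_acc = m[, 4],
    bit_score = score, evalue = ev, region_ref = m[, 1])
  gr
}

.emptyHitGr <- function() {
  GenomicRanges::GRanges(
    hit_id = character(), model_class = character(),
    model_acc = character(), bit_score = numeric(), evalue = numeric(),
    region_ref = character())
}

#' Write hits in Infernal tblout format
#'
#' Emits the 18-column `--tblout` dialect accepted by [readTblout()];
#' reading the written file back reproduces the hit coordinates,
#' strands, scores and E-values exactly.
#'
#' @param hits a hit `GRanges` (see [readTblout()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#target name", "accession", "query name", "accession",
                   "mdl", "mdl from", "mdl to", "seq from", "seq to",
                   "strand", "trunc", "pass", "gc", "bias", "score",
                   "E-value", "inc", "description of target",
                   sep = "\t"), con)
  if (!length(hits)) return(invisible(path))
  str <- as.character(GenomicRanges::strand(hits))
  from <- ifelse(str == "-", GenomicRanges::end(hits),
                 GenomicRanges::start(hits))
  to <- ifelse(str == "-", GenomicRanges::start(hits),
               GenomicRanges::end(hits))
  rows <- paste(as.character(GenomicRanges::seqnames(hits)), "-",
                hits$model_class, hits$model_acc, "cm", 1,
                GenomicRanges::width(hits), from, to, str, "no", 1,
                "0.50", "0.0",
                format(hits$bit_score, digits = 15, trim = TRUE),
                format(hits$evalue, digits = 15, trim = TRUE),
                "!", "-", sep = " ")
  writeLines(rows, con)
  invisible(path)
}
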