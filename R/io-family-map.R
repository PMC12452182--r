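# Riboswitch class -> ligand-family mapping.

#' Read a riboswitch class-to-family mapping
#'
#' The map groups covariance-model classes by the nature of the ligand
#' their aptamer senses (e.g. the SAM family collects SAM, SAM-IV, SAH,
#' SAM_alpha, SAM-I-IV, SAM-III, SAM-SAH, SAM_V and SAM_VI).  Class
#' names are matched case-sensitively; querying an unmapped class yields
#' `NA` and the caller decides the fallback.
#'
#' @param path two-column TSV with header `class family`.
#' @return a named character vector: `map[class] == family`.
#' @seealso [riboswitchFamilyMap()] for the packaged map.
#' @export
readFamilyMap <- function(path) {
  if (!file.exists(path)) stopf("family map not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!identical(names(dt), c("class", "family")))
    stopf("%s: expected header 'class<TAB>family'", path)
  dup <- dt[, .(nfam = data.table::uniqueN(family)), by = class]
  if (any(dup$nfam > 1L))
    stopf("%s: class '%s' mapped to conflicting families", path,
          dup$class[dup$nfam > 1L][1])
  dt <- unique(dt)
  setNames(dt$family, dt$class)
}

#' The packaged riboswitch family map
#'
#' A synthetic reconstruction of the 50-class, 27-family grouping of
#' Rfam 14.0-era riboswitch aptamer classes by ligand: the SAM and
#' c-di-GMP family memberships and the named single-member families
#' (T-box, TPP, FMN) follow the published description, the remaining
#' assignments are a plausible reconstruction.  Shipped as
#' `inst/extdata/riboswitch_families_synthetic.tsv`.
#'
#' @return a named character vector of 50 classes over 27 families.
#' @examples
#' fam <- riboswitchFamilyMap()
#' length(fam)          # 50 classes
#' length(unique(fam))  # 27 families
#' @export
riboswitchFamilyMap <- function() {
  readFamilyMap(system.file("extdata", "riboswitch_families_synthetic.tsv",
                            package = "riboArch", mustWork = TRUE))
}

#' Attach ligand families to aptamer hits
#'
#' @param hits a hit `GRanges` (see [readTblout()]).
#' @param familyMap named character vector from [readFamilyMap()].
#' @param unknown fallback family for unmapped classes: `"class"` reuses
#'   the class name, `"na"` records `NA`.
#' @return `hits` with a `family` metadata column.
#' @export
assignFamilies <- function(hits, familyMap = riboswitchFamilyMap(),
                           unknown = c("class", "na")) {
  unknown <- match.arg(unknown)
  fam <- unname(familyMap[hits$model_class])
  if (unknown == "class") {
    miss <- is.na(fam)
    fam[miss] <- hits$model_class[miss]
  }
  hits$family <- fam
  hits
}
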