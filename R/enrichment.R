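# Hypergeometric enrichment analyses over phyla, riboswitch families
# and COGs.  Each analysis id (S6..S19) names one row of the study's
# catalogue of tests; a task is one stratum of one analysis, described
# by the classic (N, K, n, k) quadruple.

.ANALYSIS_IDS <- c("S6", "S7", "S9", "S10", "S11", "S12", "S13",
                   "S14", "S15", "S16", "S17", "S18", "S19")

#' Upper-tail hypergeometric probability
#'
#' The probability of observing the same or a greater number of
#' successes: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (population
#' `N` with `K` successes, draw of size `n`).  Computed with
#' [stats::phyper()]; `k = 0` gives 1 exactly.  Vectorised over all
#' four arguments.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n draw (group) size.
#' @param k observed successes in the draw.
#' @return `P(X >= k)`, in `[0, 1]`.
#' @examples
#' hypergeomUpperTail(10, 5, 4, 4)  # 5/210
#' hypergeomUpperTail(1000, 20, 100, 10)
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  bad <- K < 0 | K > N | n < 0 | n > N | k < 0 | k > pmin(n, K)
  if (any(bad))
    stopf("invalid hypergeometric task: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Contiguity predicates on an aptamer table.
.isContig <- function(cls) cls %in% c("tandem", "adjacent", "mixed")
.isTandem <- function(cls) cls == "tandem"
.isAdjacent <- function(cls) cls == "adjacent"

#' Assemble one aptamer-level analysis table
#'
#' Flattens classified groups into one row per aptamer instance with
#' the annotations every enrichment analysis strata over: ligand
#' family, phylum, regulated gene, its COG and the group class.  The
#' `genes` table supplies phylum and COG via the regulated gene.
#'
#' @param genes gene `GRanges` (see [readGeneTable()]) or a data.frame
#'   with columns `gene_id`, `genome_id`, `phylum`, `cog_id`.
#' @param groups a classified [ContiguousGroupSet-class].
#' @return a data.frame: `hit_id`, `family`, `genome_id`, `gene_id`,
#'   `phylum`, `cog_id`, `group_class`.
#' @export
buildAnalysisTable <- function(genes, groups) {
  gt <- .asGeneDF(genes)
  apt <- groups@aptamers
  g <- groups@groups
  gene <- vapply(g$regulated_gene_ids[apt$group], function(x)
    as.character(x)[1], character(1))
  genome <- as.character(g$genome_id)[apt$group]
  key <- paste(genome, gene)
  m <- match(key, paste(gt$genome_id, gt$gene_id))
  data.frame(
    hit_id = as.character(apt$hit_id),
    family = as.character(apt$family),
    genome_id = genome,
    gene_id = gene,
    phylum = gt$phylum[m],
    cog_id = gt$cog_id[m],
    group_class = as.character(g$group_class)[apt$group],
    stringsAsFactors = FALSE)
}

.asGeneDF <- function(genes) {
  if (is(genes, "GRanges"))
    data.frame(gene_id = as.character(genes$gene_id),
               genome_id = as.character(genes$genome_id),
               phylum = as.character(genes$phylum),
               cog_id = as.character(genes$cog_id),
               stringsAsFactors = FALSE)
  else as.data.frame(genes)
}

#' Build the hypergeometric tasks of one analysis
#'
#' Maps the analysis catalogue onto count quadruples.  Phylum analyses
#' (S6 riboswitches, S7 contiguous, S9 tandem, S10 adjacent aptamers)
#' count riboswitch instances against gene totals per phylum; family
#' analyses (S11 contiguous, S12 tandem, S13 adjacent) count riboswitch
#' instances per ligand family; S14/S15 stratify family counts within
#' phyla; COG analyses (S16/S18 overall, S17/S19 within phyla) count
#' distinct regulated genes, a gene regulated by several aptamers
#' counting once.  Empty strata (`n = 0`) are not emitted.
#'
#' @param analysis one of `"S6"`, `"S7"`, `"S9"`..`"S19"`.
#' @param genes gene table (see [buildAnalysisTable()]).
#' @param aptamers aptamer analysis table from [buildAnalysisTable()]
#'   (or the equivalent columns from a simulation).
#' @return a data.frame of tasks: `analysis`, `stratum`, `N`, `K`, `n`,
#'   `k`.
#' @export
buildEnrichmentTasks <- function(analysis, genes, aptamers) {
  if (!analysis %in% .ANALYSIS_IDS)
    stopf("unknown analysis id '%s'", analysis)
  gt <- data.table::as.data.table(.asGeneDF(genes))
  at <- data.table::as.data.table(aptamers)
  task <- function(stratum, N, K, n, k)
    if (length(stratum)) data.frame(analysis = analysis,
                                    stratum = stratum, N = N, K = K,
                                    n = n, k = k,
                                    stringsAsFactors = FALSE)
    else NULL

  if (analysis %in% c("S6", "S7", "S9", "S10")) {
    sel <- switch(analysis, S6 = rep(TRUE, nrow(at)),
                  S7 = .isContig(at$group_class),
                  S9 = .isTandem(at$group_class),
                  S10 = .isAdjacent(at$group_class))
    genesByPhy <- gt[, .(n = .N), by = phylum]
    aptByPhy <- at[sel, .(k = .N), by = phylum]
    tab <- merge(genesByPhy, aptByPhy, by = "phylum", all.x = TRUE)
    tab[is.na(k), k := 0L]
    return(task(tab$phylum, nrow(gt), sum(sel), tab$n, tab$k))
  }

  if (analysis %in% c("S11", "S12", "S13")) {
    sel <- switch(analysis, S11 = .isContig(at$group_class),
                  S12 = .isTandem(at$group_class),
                  S13 = .isAdjacent(at$group_class))
    byFam <- at[, .(n = .N), by = family]
    selFam <- at[sel, .(k = .N), by = family]
    tab <- merge(byFam, selFam, by = "family", all.x = TRUE)
    tab[is.na(k), k := 0L]
    return(task(tab$family, nrow(at), sum(sel), tab$n, tab$k))
  }

  if (analysis %in% c("S14", "S15")) {
    byFam <- at[, .(K = .N), by = family]
    byPhy <- at[, .(n = .N), by = phylum]
    inner <- if (analysis == "S14") at
      else at[.isContig(at$group_class)]
    cell <- inner[, .(k = .N), by = .(family, phylum)]
    grid <- data.table::CJ(family = byFam$family, phylum = byPhy$phylum)
    tab <- merge(grid, cell, by = c("family", "phylum"), all.x = TRUE)
    tab[is.na(k), k := 0L]
    tab <- merge(tab, byFam, by = "family")
    tab <- merge(tab, byPhy, by = "phylum")
    return(task(paste(tab$family, tab$phylum, sep = "|"),
                nrow(at), tab$K, tab$n, tab$k))
  }

  # COG analyses: distinct regulated genes
  regSel <- if (analysis %in% c("S16", "S17")) rep(TRUE, nrow(at))
    else .isContig(at$group_class)
  reg <- unique(at[regSel, .(genome_id, gene_id)])
  gt[, regulated := paste(genome_id, gene_id) %in%
       paste(reg$genome_id, reg$gene_id)]
  gtc <- gt[!is.na(cog_id) & cog_id != ""]
  if (analysis %in% c("S16", "S18")) {
    byCog <- gtc[, .(n = .N, k = sum(regulated)), by = cog_id]
    return(task(byCog$cog_id, nrow(gt), sum(gt$regulated),
                byCog$n, byCog$k))
  }
  # S17 / S19: population is the COG, group the phylum within it
  byCog <- gtc[, .(N = .N, K = sum(regulated)), by = cog_id]
  cell <- gtc[, .(n = .N, k = sum(regulated)), by = .(cog_id, phylum)]
  tab <- merge(cell, byCog, by = "cog_id")
  task(paste(tab$cog_id, tab$phylum, sep = "|"),
       tab$N, tab$K, tab$n, tab$k)
}

#' Run a batch of enrichment analyses
#'
#' Builds the tasks of every requested analysis, checks the tally
#' consistency (stratum successes can never sum past the population
#' successes), computes upper-tail p-values and fold enrichments and
#' returns the results sorted by (analysis, p-value).  Raw p-values are
#' the primary output; a Benjamini-Hochberg column can be added as a
#' convenience but never drives the ordering.
#'
#' @param analyses character vector of analysis ids.
#' @param genes gene table.
#' @param aptamers aptamer analysis table (see [buildAnalysisTable()]).
#' @param bh add a `p_bh` column of within-analysis BH-adjusted values.
#' @return a data.frame: `analysis`, `stratum`, `N`, `K`, `n`, `k`,
#'   `fold`, `p_value` (and optionally `p_bh`).
#' @export
runEnrichment <- function(analyses, genes, aptamers, bh = FALSE) {
  tasks <- do.call(rbind, lapply(analyses, buildEnrichmentTasks,
                                 genes = genes, aptamers = aptamers))
  if (is.null(tasks) || !nrow(tasks))
    return(data.frame(analysis = character(0), stratum = character(0),
                      N = integer(0), K = integer(0), n = integer(0),
                      k = integer(0), fold = numeric(0),
                      p_value = numeric(0)))
  popKey <- paste(tasks$analysis, tasks$N, tasks$K)
  overs <- tapply(tasks$k, popKey, sum) >
    tapply(tasks$K, popKey, function(x) x[1])
  if (any(overs))
    stopf("tally inconsistency: stratum successes exceed population successes (%s)",
          names(overs)[overs][1])
  tasks$fold <- ifelse(tasks$n > 0 & tasks$K > 0,
                       (tasks$k / tasks$n) / (tasks$K / tasks$N), NA_real_)
  tasks$p_value <- hypergeomUpperTail(tasks$N, tasks$K, tasks$n, tasks$k)
  if (bh)
    tasks$p_bh <- stats::ave(tasks$p_value, tasks$analysis,
                             FUN = function(p) stats::p.adjust(p, "BH"))
  tasks[order(tasks$analysis, tasks$p_value), , drop = FALSE]
}

#' Riboswitch-per-gene prevalence percentages
#'
#' The simple worked statistic of differential riboswitch prevalence:
#' riboswitch count divided by gene count, as a percentage, per row of
#' a count table.
#'
#' @param counts data.frame with columns `riboswitches` and `genes`
#'   (and any label columns, which are passed through).
#' @return `counts` with a `percent` column added.
#' @examples
#' riboswitchPrevalence(data.frame(stratum = "all",
#'                                 riboswitches = 36, genes = 10000))
#' @export
riboswitchPrevalence <- function(counts) {
  stopifnot(all(c("riboswitches", "genes") %in% names(counts)))
  counts$percent <- 100 * counts$riboswitches / counts$genes
  counts
}
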