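test_that("T-run detection merges windows and clips to T content", {
  expect_equal(nrow(findTRuns("AAAAAAAA")), 0)
  r <- findTRuns("AATTTTTAA")
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(3, 7))
  # brute-force: every 6-nt window with >= 5 T, interval union
  s <- "TTTTTATTTTT"
  wins <- vapply(1:(nchar(s) - 5), function(i)
    sum(strsplit(substr(s, i, i + 5), "")[[1]] == "T") >= 5, logical(1))
  expect_true(all(wins))
  r2 <- findTRuns(s)
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(1, 11))
  # two separated runs stay separate
  r3 <- findTRuns(paste0("TTTTTT", strrep("A", 20), "TTTTTT"))
  expect_equal(nrow(r3), 2)
})

test_that("best hairpin equals the exhaustive single-stem oracle", {
  params <- terminatorParams()
  # canonical fixture
  s <- "GGGGGAAAACCCCC"
  fold <- bestHairpin(s, params)
  expect_equal(fold$dg, oracleBestHairpin(s))
  expect_equal(nrow(fold$pairs), 5)
  expect_null(bestHairpin("AAAAAAAAAAAA", params))
  # adversarial fixtures: bulges, GU pairs, ties
  fixtures <- c("GGGAGGAAAACCCCCC", "GGTGGAAAACCACC", "GCGCGAAAACGCGC",
                "GGGGAAAACCCCAAAGGGGAAAACCCC")
  for (s in fixtures) {
    fold <- bestHairpin(s, params)
    dg <- if (is.null(fold)) Inf else fold$dg
    expect_equal(dg, oracleBestHairpin(s), info = s)
  }
  # random 15-25-mers: DP optimum matches enumeration, and no
  # enumerated structure beats it
  set.seed(202)
  for (i in 1:150) {
    s <- randSeq(sample(15:25, 1), gc = runif(1, 0.3, 0.7))
    fold <- bestHairpin(s, params)
    dg <- if (is.null(fold)) Inf else fold$dg
    expect_equal(dg, oracleBestHairpin(s), info = s)
  }
})

test_that("returned folds satisfy their structural invariants", {
  params <- terminatorParams()
  set.seed(77)
  for (i in 1:80) {
    s <- randSeq(sample(18:40, 1), gc = 0.6)
    fold <- bestHairpin(s, params)
    if (is.null(fold)) next
    p <- fold$pairs
    expect_gte(nrow(p), params@minStem)
    # nested, non-crossing single stem
    expect_true(all(diff(p[, 1]) > 0))
    expect_true(all(diff(p[, 2]) < 0))
    expect_true(all(p[, 2] - p[, 1] > 0))
    # terminal loop length
    expect_gte(p[nrow(p), 2] - p[nrow(p), 1] - 1, params@minLoop)
    # dg equals the oracle's scoring of exactly these pairs
    ch <- strsplit(chartr("T", "U", s), "")[[1]]
    expect_equal(fold$dg, oracleScoreStem(ch, p))
  }
})

test_that("terminator calls respect geometry, threshold and nearest rule", {
  term <- paste0(strrep("G", 8), "AAAA", strrep("C", 8), strrep("T", 8))
  params <- terminatorParams()
  # poly-A window -> none
  expect_null(callTerminator(strrep("A", 50), 0, params))
  # canonical terminator, gap 0
  call <- callTerminator(paste0(term, strrep("A", 22)), 0, params)
  expect_equal(call$gap, 0)
  expect_lt(call$dg, -10)
  expect_equal(call$dg, oracleBestHairpin(substr(term, 1, 20)))
  expect_equal(c(call$t_run_start, call$t_run_end), c(21, 28))
  # same hairpin without the T-run -> none
  noRun <- paste0(strrep("G", 8), "AAAA", strrep("C", 8), strrep("A", 8))
  expect_null(callTerminator(noRun, 0, params))
  # stem too weak (short AU stem) -> below threshold, none
  weak <- paste0("AUAU", "AAAA", "AUAU", strrep("T", 8))
  expect_null(callTerminator(chartr("U", "T", weak), 0, params))
  # translation invariance: shifting the aptamer end shifts coordinates
  shift <- 13
  host <- paste0(strrep("A", shift), term, strrep("A", 22))
  call2 <- callTerminator(host, shift, params)
  expect_equal(call2$t_run_start, call$t_run_start + shift)
  expect_equal(call2$hairpin_end, call$hairpin_end + shift)
  expect_equal(call2$dg, call$dg)
})

test_that("inter-aptamer scanning clips windows and counts junctions", {
  term <- paste0(strrep("G", 8), "AAAA", strrep("C", 8), strrep("T", 8))
  mkGroup <- function(gapSeqs, aptLen = 60) {
    seqs <- character(0)
    starts <- integer(0); at <- 1L
    for (i in seq_along(gapSeqs)) {
      starts <- c(starts, at)
      seqs <- c(seqs, strrep("A", aptLen), gapSeqs[[i]])
      at <- at + aptLen + nchar(gapSeqs[[i]])
    }
    starts <- c(starts, at)
    seqs <- c(seqs, strrep("A", aptLen), strrep("A", 30))
    region <- makeRegion(paste(seqs, collapse = ""))
    n <- length(starts)
    hits <- makeHits(regionIds(region), starts,
                     starts + aptLen - 1L,
                     rep("T-box", n), seq(50, 40, length.out = n))
    groups <- groupContiguous(hits, region)
    list(groups = groups, region = region)
  }
  # 8-nt junction: geometrically impossible
  g1 <- mkGroup(list(strrep("A", 8)))
  expect_equal(nrow(scanInterAptamer(g1$groups, g1$region)), 0)
  # 45-nt junction containing the canonical terminator
  g2 <- mkGroup(list(paste0(term, strrep("A", 17))))
  calls <- scanInterAptamer(g2$groups, g2$region)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$junction, 1)
  expect_lt(calls$dg, -10)
  # triple with terminators after aptamers 1 and 2
  g3 <- mkGroup(list(paste0(term, strrep("A", 10)),
                     paste0(term, strrep("A", 10))))
  calls3 <- scanInterAptamer(g3$groups, g3$region)
  expect_equal(sort(calls3$junction), c(1, 2))
})

test_that("shuffled planted-terminator windows rarely trigger calls", {
  term <- paste0(strrep("G", 8), "AAAA", strrep("C", 8), strrep("T", 8))
  set.seed(303)
  hits <- 0; n <- 200
  for (i in 1:n) {
    host <- paste0(randSeq(10), term, randSeq(12))
    sh <- dinucleotideShuffle(host, seed = i)
    if (!is.null(callTerminator(sh, 0))) hits <- hits + 1
  }
  expect_lt(hits / n, 0.10)
})
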