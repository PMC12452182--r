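test_that("dinucleotide shuffle preserves the dinucleotide multiset", {
  set.seed(101)
  for (rep in 1:300) {
    len <- sample(2:120, 1)
    s <- randSeq(len, gc = runif(1, 0.2, 0.8))
    out <- dinucleotideShuffle(s, seed = rep)
    expect_identical(nchar(out), nchar(s))
    expect_identical(oracleDinucs(out), oracleDinucs(s))
    expect_identical(substr(out, 1, 1), substr(s, 1, 1))
    expect_identical(substr(out, len, len), substr(s, len, len))
  }
})

test_that("shuffle is reproducible and rejects bad input", {
  s <- randSeq(200)
  expect_identical(dinucleotideShuffle(s, seed = 7),
                   dinucleotideShuffle(s, seed = 7))
  expect_identical(dinucleotideShuffle("AAAA"), "AAAA")
  expect_error(dinucleotideShuffle("A"), "length")
  expect_error(dinucleotideShuffle("ACGN"), "non-ACGT")
  # seeded call leaves the caller's RNG stream untouched
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(dinucleotideShuffle(s, seed = 3))
  expect_identical(runif(1), before)
})

test_that("short-sequence shuffles reach exactly the valid set", {
  for (s in c("ACGT", "GAATTC", "AGAGA", "CATTAG", "TTGACAA")) {
    valid <- oracleShuffleSet(s)
    seen <- unique(vapply(1:400, function(i)
      dinucleotideShuffle(s, seed = i), character(1)))
    expect_setequal(seen, valid)
  }
  # every output of "ACGT" begins with A and ends with T
  outs <- vapply(1:200, function(i) dinucleotideShuffle("ACGT", seed = i),
                 character(1))
  expect_true(all(substr(outs, 1, 1) == "A" & substr(outs, 4, 4) == "T"))
})

test_that("cutoff calibration equals brute-force re-enumeration", {
  set.seed(33)
  regions <- vapply(1:3, function(i) randSeq(80, gc = 0.6), character(1))
  toyScanner <- function(s) {
    # score = 10 * count of CCCC occurrences (deterministic toy oracle)
    n <- length(gregexpr("CCCC", s, fixed = TRUE)[[1]])
    hit <- gregexpr("CCCC", s, fixed = TRUE)[[1]][1] != -1
    if (!hit) numeric(0) else rep(10, n)
  }
  params <- shuffleParams(nShuffles = 5, seed = 42)
  got <- calibrateCutoff("toy", regions, toyScanner, params)
  # independent re-enumeration with the same substream derivation
  scores <- numeric(0)
  for (i in seq_along(regions)) for (r in 1:5) {
    sh <- dinucleotideShuffle(regions[[i]],
                              seed = riboArch:::deriveSeed(42, i, r))
    scores <- c(scores, toyScanner(sh))
  }
  if (length(scores)) {
    expect_equal(got$cutoff_bits, max(scores))
    expect_equal(got$n_random_hits, length(scores))
  } else {
    expect_equal(got$cutoff_bits, 0)
  }
  # no hits anywhere -> documented floor
  none <- calibrateCutoff("toy", regions, function(s) numeric(0), params)
  expect_equal(none$cutoff_bits, 0)
  expect_equal(none$n_random_hits, 0)
  expect_error(calibrateCutoff("toy", character(0), toyScanner, params),
               "empty")
})

test_that("calibration is monotone in the region collection", {
  set.seed(44)
  regions <- vapply(1:4, function(i) randSeq(60), character(1))
  sc <- function(s) nchar(gsub("[^G]", "", s)) / 10  # deterministic
  params <- shuffleParams(nShuffles = 3, seed = 9)
  c2 <- calibrateCutoff("toy", regions[1:2], sc, params)$cutoff_bits
  c4 <- calibrateCutoff("toy", regions, sc, params)$cutoff_bits
  expect_gte(c4, c2)
})

test_that("cutoff filtering is strict and flags unknown models", {
  hits <- makeHits("igr1", c(1, 200, 400), c(100, 300, 500),
                   c("SAM", "SAM", "T-box"), c(30.0, 30.1, 50))
  kept <- applyCutoffs(hits, c(SAM = 30.0))
  expect_setequal(kept$bit_score, c(30.1, 50))
  expect_false(kept$cutoff_applied[kept$model_class == "T-box"])
  expect_true(kept$cutoff_applied[kept$model_class == "SAM"])
  # 5 hits, cutoffs filtering 2 -> 3 survive
  h5 <- makeHits("igr1", seq(1, 900, 200), seq(100, 1000, 200),
                 rep("SAM", 5), c(10, 20, 31, 40, 50))
  expect_length(applyCutoffs(h5, c(SAM = 30)), 3)
})
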