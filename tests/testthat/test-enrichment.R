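test_that("upper-tail hypergeometric matches brute-force summation", {
  # worked examples
  expect_equal(hypergeomUpperTail(10, 5, 4, 4), 5 / 210)
  expect_equal(hypergeomUpperTail(4, 2, 2, 1), 5 / 6)
  expect_equal(hypergeomUpperTail(100, 10, 20, 0), 1)
  # drawing the whole population is certain
  expect_equal(hypergeomUpperTail(12, 7, 12, 7), 1)
  # moderate grid against choose() summation
  for (N in c(5, 11, 23, 40)) for (K in c(0, 2, N %/% 2, N)) {
    for (n in c(0, 3, N %/% 3, N)) {
      pmf <- choose(K, 0:min(n, K)) * choose(N - K, n - (0:min(n, K))) /
        choose(N, n)
      for (k in 0:min(n, K)) {
        expect_equal(hypergeomUpperTail(N, K, n, k),
                     sum(pmf[(k + 1):length(pmf)]),
                     tolerance = 1e-12)
      }
    }
  }
  # symmetry p(N,K,n,k) == p(N,n,K,k) and monotonicity in k
  for (i in 1:50) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- 0:min(n, K)
    p <- hypergeomUpperTail(N, K, n, ks)
    expect_equal(p, hypergeomUpperTail(N, n, K, ks))
    expect_true(all(diff(p) <= 1e-15))
  }
  expect_error(hypergeomUpperTail(10, 12, 3, 1), "invalid")
  expect_error(hypergeomUpperTail(10, 5, 4, 5), "invalid")
})

test_that("task construction follows the analysis catalogue", {
  # two-phylum toy: A has 100 genes / 10 regulated, B 900 / 10
  genes <- data.frame(
    gene_id = paste0("g", 1:1000), genome_id = "x",
    phylum = rep(c("A", "B"), c(100, 900)),
    cog_id = NA_character_)
  apt <- data.frame(
    hit_id = paste0("h", 1:20), family = "T-box", genome_id = "x",
    gene_id = paste0("g", c(1:10, 101:110)),
    phylum = rep(c("A", "B"), each = 10),
    cog_id = NA_character_, group_class = "single")
  t6 <- buildEnrichmentTasks("S6", genes, apt)
  a <- t6[t6$stratum == "A", ]
  expect_equal(c(a$N, a$K, a$n, a$k), c(1000, 20, 100, 10))
  # empty stratum not emitted
  genes2 <- rbind(genes, data.frame(gene_id = "g1001", genome_id = "y",
                                    phylum = "C", cog_id = NA))
  t6b <- buildEnrichmentTasks("S6", genes2, apt)
  expect_equal(t6b[t6b$stratum == "C", ]$k, 0)
  expect_error(buildEnrichmentTasks("S8", genes, apt), "unknown")
})

test_that("family and COG tasks tally the right units", {
  # family F: 50 riboswitches of which 20 contiguous; others 950/30
  apt <- data.frame(
    hit_id = paste0("h", 1:1000),
    family = rep(c("F", "G"), c(50, 950)),
    genome_id = "x", gene_id = paste0("g", 1:1000), phylum = "A",
    cog_id = NA_character_,
    group_class = c(rep(c("tandem", "single"), c(20, 30)),
                    rep(c("adjacent", "single"), c(30, 920))))
  genes <- data.frame(gene_id = paste0("g", 1:1000), genome_id = "x",
                      phylum = "A", cog_id = NA_character_)
  t11 <- buildEnrichmentTasks("S11", genes, apt)
  f <- t11[t11$stratum == "F", ]
  expect_equal(c(f$N, f$K, f$n, f$k), c(1000, 50, 50, 20))
  # S12 counts only tandem among contiguous
  t12 <- buildEnrichmentTasks("S12", genes, apt)
  expect_equal(t12[t12$stratum == "F", ]$k, 20)
  expect_equal(t12[t12$stratum == "F", ]$K, 20)
  t13 <- buildEnrichmentTasks("S13", genes, apt)
  expect_equal(t13[t13$stratum == "F", ]$k, 0)
  expect_equal(t13[t13$stratum == "G", ]$k, 30)

  # COG row: gene regulated by two aptamers counts once
  genes3 <- data.frame(gene_id = paste0("g", 1:10), genome_id = "x",
                       phylum = "A",
                       cog_id = rep(c("COG1", "COG2"), each = 5))
  apt3 <- data.frame(hit_id = c("h1", "h2", "h3"), family = "T-box",
                     genome_id = "x", gene_id = c("g1", "g1", "g6"),
                     phylum = "A", cog_id = c("COG1", "COG1", "COG2"),
                     group_class = c("tandem", "tandem", "single"))
  t16 <- buildEnrichmentTasks("S16", genes3, apt3)
  c1 <- t16[t16$stratum == "COG1", ]
  expect_equal(c(c1$N, c1$K, c1$n, c1$k), c(10, 2, 5, 1))
  # S18 restricts to contiguous-regulated genes
  t18 <- buildEnrichmentTasks("S18", genes3, apt3)
  expect_equal(t18[t18$stratum == "COG1", ]$k, 1)
  expect_equal(t18[t18$stratum == "COG2", ]$k, 0)
  # S17: population is the COG itself
  t17 <- buildEnrichmentTasks("S17", genes3, apt3)
  c1p <- t17[t17$stratum == "COG1|A", ]
  expect_equal(c(c1p$N, c1p$K, c1p$n, c1p$k), c(5, 1, 5, 1))
})

test_that("batch runner composes, sorts and bounds tallies", {
  genes <- data.frame(gene_id = paste0("g", 1:200), genome_id = "x",
                      phylum = rep(c("A", "B"), each = 100),
                      cog_id = NA_character_)
  apt <- data.frame(hit_id = paste0("h", 1:12), family = "TPP",
                    genome_id = "x", gene_id = paste0("g", 1:12),
                    phylum = rep(c("A", "B"), c(10, 2)),
                    cog_id = NA_character_, group_class = "single")
  res <- runEnrichment(c("S6", "S11"), genes, apt, bh = TRUE)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$p_value[res$analysis == "S6"],
               sort(res$p_value[res$analysis == "S6"]))
  a <- res[res$analysis == "S6" & res$stratum == "A", ]
  expect_equal(a$p_value, hypergeomUpperTail(200, 12, 100, 10))
  # all-zero strata give p = 1
  apt0 <- apt[0, ]
  res0 <- runEnrichment("S6", genes, apt0)
  expect_true(all(res0$p_value == 1))
})

test_that("a planted five-fold phylum enrichment wins analysis S6", {
  cfg <- simConfig(nPhyla = 10, genomesPerPhylum = 5,
                   genesPerGenome = 400, baseRiboswitchRate = 0.01,
                   phylumRateMultipliers = c(5, rep(1, 9)),
                   cogEnrichment = numeric(0), seed = 1)
  sim <- simulateCollection(cfg, level = "counts")
  res <- runEnrichment("S6",
                       sim$genes[c("gene_id", "genome_id", "phylum",
                                   "cog_id")],
                       sim$aptamers)
  expect_equal(res$stratum[which.min(res$p_value)], "Phylum01")
  expect_lt(min(res$p_value), 1e-6)
})
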