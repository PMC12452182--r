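test_that("simulation is deterministic and honours the architecture mix", {
  cfg <- simConfig(nPhyla = 2, genomesPerPhylum = 2, genesPerGenome = 60,
                   seed = 5)
  s1 <- simulateCollection(cfg)
  s2 <- simulateCollection(cfg)
  expect_identical(as.character(regionSeqs(s1$regions)),
                   as.character(regionSeqs(s2$regions)))
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.data.frame(s1$genes), as.data.frame(s2$genes))
  # all-singles config produces no multi-aptamer groups
  cfgS <- simConfig(nPhyla = 2, genomesPerPhylum = 1, genesPerGenome = 50,
                    architectureMix = c(single = 1, tandem_pair = 0,
                                        adjacent_pair = 0,
                                        tandem_triple = 0), seed = 8)
  sS <- simulateCollection(cfgS)
  expect_true(all(sS$truth$group_class == "single"))
  # invalid gap configuration is rejected
  expect_error(simConfig(adjacentGapRange = c(5, 25)), "below")
  expect_error(simConfig(tandemGapRange = c(15, 50)), "exceed")
})

test_that("planted regulated-gene count is binomially plausible", {
  cfg <- simConfig(nPhyla = 1, genomesPerPhylum = 1,
                   genesPerGenome = 1000, baseRiboswitchRate = 0.05,
                   cogEnrichment = numeric(0), seed = 23)
  sim <- simulateCollection(cfg, level = "counts")
  nReg <- sum(sim$genes$regulated)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.05)
  expect_gte(nReg, bounds[1])
  expect_lte(nReg, bounds[2])
})

test_that("terminator planting is detectable by construction", {
  # 60-nt poly-A host, plant at position 11 -> exactly one call
  host <- plantTerminator(strrep("A", 60), 11)
  expect_equal(nchar(host), 60)
  call <- callTerminator(host, 0)
  expect_false(is.null(call))
  expect_lt(call$dg, -10)
  expect_error(plantTerminator(strrep("A", 30), 20), "no room")
  # two plants in one window: the first (nearest run) is reported
  host2 <- plantTerminator(plantTerminator(strrep("A", 100), 1), 41)
  call2 <- callTerminator(host2, 0)
  expect_equal(call2$t_run_start, 21)
})

test_that("emitted files parse cleanly through the package readers", {
  sim <- simulateCollection(simConfig(nPhyla = 2, genomesPerPhylum = 1,
                                      genesPerGenome = 50, seed = 31),
                            nDecoys = 5)
  d <- tempfile()
  writeCollection(sim, d)
  genes <- readGeneTable(file.path(d, "genes.tsv"))
  expect_equal(length(genes), length(sim$genes))
  hits <- readTblout(file.path(d, "hits.tbl"))
  expect_equal(length(hits), length(sim$hits))
  expect_equal(sort(hits$bit_score), sort(sim$hits$bit_score))
  seqs <- Biostrings::readDNAStringSet(file.path(d, "regions.fasta"))
  expect_equal(length(seqs), length(sim$regions))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth), nrow(sim$truth))
  # decoys fall below a 30-bit nominal cutoff
  kept <- applyCutoffs(hits, setNames(rep(30, 50),
                                      unique(hits$model_class)))
  expect_equal(length(kept), length(hits) - 5)
})

test_that("count-level and full-level simulations agree in structure", {
  cfg <- simConfig(nPhyla = 2, genomesPerPhylum = 2, genesPerGenome = 80,
                   seed = 41)
  full <- simulateCollection(cfg)
  # aptamer table group classes match truth group by group
  m <- match(paste(full$aptamers$genome_id, full$aptamers$gene_id),
             paste(full$truth$genome_id, full$truth$gene_id))
  expect_false(anyNA(m))
  expect_equal(full$aptamers$group_class, full$truth$group_class[m])
  counts <- simulateCollection(cfg, level = "counts")
  expect_true(all(c("gene_id", "genome_id", "phylum", "cog_id",
                    "regulated") %in% names(counts$genes)))
  expect_equal(nrow(counts$genes), 2 * 2 * 80)
})
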