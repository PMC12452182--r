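test_that("hit deduplication keeps the best of redundant matches", {
  # two overlapping SAM-class hits: higher score survives
  h <- makeHits("igr1", c(10, 12), c(110, 108), c("SAM", "SAM-IV"),
                c(40, 35))
  kept <- dedupeHits(h)
  expect_length(kept, 1)
  expect_equal(kept$bit_score, 40)
  # non-overlapping hits both retained
  h2 <- makeHits("igr1", c(1, 200), c(100, 300), c("SAM", "TPP"),
                 c(40, 35))
  expect_length(dedupeHits(h2), 2)
  # three mutually overlapping hits, scores 10/20/30 -> only 30;
  # cross-checked against a pairwise-overlap closure oracle
  h3 <- makeHits("igr1", c(10, 12, 14), c(110, 112, 114),
                 c("a", "b", "c"), c(10, 20, 30))
  kept3 <- dedupeHits(h3)
  expect_length(kept3, 1)
  expect_equal(kept3$bit_score, 30)
  overlapFrac <- function(i, j, gr) {
    ov <- min(GenomicRanges::end(gr)[c(i, j)]) -
      max(GenomicRanges::start(gr)[c(i, j)]) + 1
    ov / min(GenomicRanges::width(gr)[c(i, j)])
  }
  expect_true(all(combn(3, 2, function(p)
    overlapFrac(p[1], p[2], h3)) > 0.5))
  # score tie resolved by E-value then model name
  h4 <- makeHits("igr1", c(10, 12), c(110, 108), c("zzz", "aaa"),
                 c(40, 40), evalues = c(1e-5, 1e-5))
  expect_equal(dedupeHits(h4)$model_class, "aaa")
})

test_that("grouping partitions hits by region with ordered junction gaps", {
  r1 <- makeRegion(strrep("A", 400), id = "igr|gA|g1", gene = "g1")
  hits <- makeHits("igr|gA|g1", c(1, 136), c(100, 235),
                   c("T-box", "T-box"), c(50, 45))
  g <- groupContiguous(hits, r1)
  expect_equal(length(g), 1)
  expect_equal(g@groups$junction_gaps[[1]], 35)
  expect_equal(g@groups$n_aptamers, 2)
  expect_equal(unlist(g@groups$regulated_gene_ids), "g1")
  # order invariance
  g2 <- groupContiguous(rev(hits), r1)
  expect_identical(groupTable(g), groupTable(g2))
  # single-hit group
  g3 <- groupContiguous(hits[1], r1)
  expect_equal(g3@groups$group_class, "single")
  expect_equal(g3@groups$homogeneity, "n/a")
  # every deduplicated hit lands in exactly one group
  sim <- simulateCollection(simConfig(nPhyla = 2, genomesPerPhylum = 2,
                                      genesPerGenome = 60, seed = 13))
  hh <- assignFamilies(dedupeHits(sim$hits))
  gg <- groupContiguous(hh, sim$regions)
  expect_equal(sum(gg@groups$n_aptamers), length(hh))
  expect_equal(length(gg), length(unique(hh$region_ref)))
  # overlapping aptamers after a failed dedup are refused
  bad <- makeHits("igr|gA|g1", c(1, 50), c(100, 150),
                  c("T-box", "TPP"), c(50, 45))
  expect_error(groupContiguous(bad, r1), "overlapping")
})

test_that("junction classification applies the 20-nt rule with terminator evidence", {
  r1 <- makeRegion(strrep("A", 500))
  mk <- function(gaps) {
    starts <- cumsum(c(1, rep(80, length(gaps))) +
                       c(0, gaps))
    hits <- makeHits(regionIds(r1), starts, starts + 79,
                     rep("T-box", length(starts)),
                     seq(60, 40, length.out = length(starts)))
    groupContiguous(hits, r1)
  }
  # gap 35 with a terminator call -> tandem, evidence recorded
  g <- mk(35)
  term <- data.frame(region_ref = regionIds(r1), junction = 1L)
  cls <- classifyGroups(g, term)
  expect_equal(cls@groups$group_class, "tandem")
  expect_true(cls@groups$terminator_evidence[[1]])
  # gap 5 -> adjacent; gap exactly 20 -> tandem (boundary)
  expect_equal(classifyGroups(mk(5))@groups$group_class, "adjacent")
  expect_equal(classifyGroups(mk(20))@groups$group_class, "tandem")
  expect_equal(classifyGroups(mk(19))@groups$group_class, "adjacent")
  # gaps 5 and 35 -> mixed
  expect_equal(classifyGroups(mk(c(5, 35)))@groups$group_class, "mixed")
  # distance rule is authoritative: no terminator does not flip tandem
  g35 <- classifyGroups(mk(35))
  expect_equal(g35@groups$group_class, "tandem")
  expect_false(g35@groups$terminator_evidence[[1]])
})

test_that("homogeneity labelling follows the family map", {
  r1 <- makeRegion(strrep("A", 500))
  mkFam <- function(models) {
    starts <- seq(1, by = 120, length.out = length(models))
    hits <- makeHits(regionIds(r1), starts, starts + 79, models,
                     seq(60, 40, length.out = length(models)))
    groupContiguous(hits, r1)
  }
  g <- labelHomogeneity(mkFam(c("T-box", "T-box")))
  expect_equal(g@groups$homogeneity, "homogeneous")
  expect_equal(g@groups$architecture_string, "T-box T-box")
  g2 <- labelHomogeneity(mkFam(c("T-box", "Guanidine-I")))
  expect_equal(g2@groups$homogeneity, "heterogeneous")
  expect_equal(g2@groups$architecture_string, "T-box Guanidine")
  # same ligand family through different model classes is homogeneous
  g3 <- labelHomogeneity(mkFam(c("SAM", "SAM-IV")))
  expect_equal(g3@groups$homogeneity, "homogeneous")
  expect_equal(g3@groups$architecture_string, "SAM SAM")
})

test_that("planted architectures are recovered exactly with clear margins", {
  sim <- simulateCollection(simConfig(seed = 17))
  hits <- assignFamilies(dedupeHits(sim$hits))
  groups <- groupContiguous(hits, sim$regions)
  terms <- scanInterAptamer(groups, sim$regions)
  groups <- labelHomogeneity(classifyGroups(groups, terms))
  gt <- groupTable(groups)
  m <- match(gt$region_ref, sim$truth$region_id)
  expect_false(anyNA(m))
  expect_equal(gt$group_class, sim$truth$group_class[m])
  expect_equal(gt$homogeneity, sim$truth$homogeneity[m])
  expect_equal(gt$architecture_string,
               gsub(",", " ", sim$truth$families[m]))
})
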