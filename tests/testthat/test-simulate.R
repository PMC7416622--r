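test_that("identical seeds give identical datasets", {
  s1 <- simOneWgd(seed = 99, nFamilies = 20)
  s2 <- simOneWgd(seed = 99, nFamilies = 20)
  expect_identical(s1$cds, s2$cds)
  expect_identical(geneTable(s1$genomes$A), geneTable(s2$genomes$A))
  expect_identical(s1$homology, s2$homology)
  expect_identical(trueAnchors(s1$truth), trueAnchors(s2$truth))
  s3 <- simOneWgd(seed = 100, nFamilies = 20)
  expect_false(identical(s1$cds, s3$cds))
})

test_that("gene ids are unique and each gene sits on exactly one scaffold", {
  sim <- simStemWgd(seed = 5, nFamilies = 25)
  g <- truthGenes(sim$truth)
  expect_false(anyDuplicated(g$gene_id) > 0)
  expect_equal(sort(names(sim$cds)), sort(g$gene_id))
  for (sp in names(sim$genomes)) {
    validObject(sim$genomes[[sp]])
  }
})

test_that("evolveSequence honours its degenerate contracts", {
  set.seed(3)
  parent <- randomDnaCds(100)
  expect_identical(evolveSequence(parent, 0)$child, parent)
  ## omega = 0: rejection forbids every nonsynonymous difference
  child <- evolveSequence(parent, 0.3, omega = 0)$child
  d <- ng86Differences(parent, child)
  expect_equal(unname(d["Nd"]), 0)
  expect_gt(unname(d["Sd"]), 0)
})

test_that("realized Ks matches the target within the stated tolerance", {
  set.seed(19)
  parent <- randomDnaCds(300)
  ks <- replicate(200, ksPair(parent, evolveSequence(parent, 0.5)$child)$ks)
  expect_gt(mean(ks), 0.425)
  expect_lt(mean(ks), 0.575)
})

test_that("realized Ks regresses on true divergence with slope near 1", {
  ## stem-WGD scenario gives a divergence ladder (0.3, 0.6, 0.9, 1.2)
  sim <- simStemWgd(seed = 23, nFamilies = 60, retention = 0.5,
                    cdsCodons = 300)
  pk <- sim$truth@pairKs
  est <- ksPairwise(sim$cds, pk[, c("gene_a", "gene_b")])
  keep <- is.finite(est$ks) & pk$true_ks <= 1.5
  fit <- stats::lm(est$ks[keep] ~ pk$true_ks[keep])
  expect_gt(coef(fit)[2], 0.85)
  expect_lt(coef(fit)[2], 1.15)
})

test_that("full retention duplicates every scaffold and gene", {
  g <- SpeciesGenome("A", data.frame(
    gene_id = sprintf("g%02d", 1:10), scaffold = "s1", rank = 0:9,
    strand = "+"))
  set.seed(1)
  d1 <- applyWgd(g, 1.0)
  expect_equal(nGenes(d1), 20L)
  expect_length(unique(geneTable(d1)$scaffold), 2L)
  ## two rounds, no loss: every original gene has 4 copies
  d2 <- applyWgd(d1, 1.0)
  expect_equal(nGenes(d2), 40L)
  expect_equal(sum(grepl("^g01(_w[0-9]+)*$", geneTable(d2)$gene_id)), 4L)
  ## retention 0 removes every duplicate
  set.seed(2)
  d0 <- applyWgd(g, 0)
  expect_equal(nGenes(d0), 10L)
})

test_that("zero-retention WGD leaves no true anchor pairs", {
  cfg <- simConfig("(A:0.75,B:0.75);",
                   wgdEvents = data.frame(branch = "A", age_ks = 1,
                                          retention = 0),
                   nFamilies = 20, seed = 8, cdsCodons = 60)
  sim <- simulateDataset(cfg)
  expect_equal(nrow(trueAnchors(sim$truth)), 0L)
})

test_that("inversions reverse a rank window and flip strands", {
  g <- SpeciesGenome("A", data.frame(
    gene_id = sprintf("g%02d", 1:10), scaffold = "s1", rank = 0:9,
    strand = "+"))
  set.seed(42)
  inv <- applyInversions(g, 1)
  gt <- geneTable(inv)
  flipped <- gt$gene_id[gt$strand == "-"]
  expect_gt(length(flipped), 0)
  ## flipped genes occupy a contiguous window in reversed order
  orig <- geneTable(g)
  win <- sort(match(flipped, orig$gene_id))
  expect_equal(win, seq(min(win), max(win)))
  newRanks <- gt$rank[match(orig$gene_id[win], gt$gene_id)]
  expect_equal(newRanks, rev(sort(newRanks)))
  ## untouched genes keep their ranks
  out <- setdiff(orig$gene_id, flipped)
  expect_equal(gt$rank[match(out, gt$gene_id)], orig$rank[match(out, orig$gene_id)])
})

test_that("infeasible WGD ages are rejected", {
  expect_error(
    simConfig("(A:0.2,B:0.2);",
              wgdEvents = data.frame(branch = "A", age_ks = 1.5,
                                     retention = 0.5)),
    "infeasible")
})

test_that("true anchor ages equal the configured event age", {
  sim <- simOneWgd(seed = 12, nFamilies = 40, ageKs = 1.0, retention = 0.5)
  ta <- trueAnchors(sim$truth)
  expect_true(all(abs(ta$true_ks - 1.0) < 1e-9))
  expect_true(all(ta$species == "A"))
})
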