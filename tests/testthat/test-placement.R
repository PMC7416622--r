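gs4 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", d1 = "D",
         o1 = "O")

test_that("family filtering drops old anchors, merges bridged families", {
  fams <- list(f1 = c("a1", "a2"), f2 = c("b1", "b2"), f3 = c("c1", "o1"))
  anch <- data.frame(gene_a = c("a1", "b1", "c1"),
                     gene_b = c("b2", "b2", "o1"),
                     ks = c(1.0, 5.2, 1.0))
  gsp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", o1 = "O")
  out <- filterFamiliesForPlacement(fams, anch, gsp, "O", maxKs = 5)
  ## the ks = 5.2 anchor is dropped before merging; (a1, b2) merges f1 + f2
  ## but the merged family lacks an outgroup gene, so only f3 survives
  expect_equal(names(out$families), "f3")
  expect_equal(out$anchors$gene_a, "c1")
  ## size cap
  big <- list(f1 = sprintf("a%03d", 1:301))
  gsp2 <- stats::setNames(rep("A", 301), big$f1)
  gsp2["a001"] <- "O"
  anch2 <- data.frame(gene_a = "a002", gene_b = "a003", ks = 1)
  expect_length(filterFamiliesForPlacement(big, anch2, gsp2, "O",
                                           maxSize = 300)$families, 0L)
  expect_length(filterFamiliesForPlacement(big, anch2, gsp2, "O",
                                           maxSize = 301)$families, 1L)
})

test_that("NJ recovers additive trees and strong splits get full support", {
  set.seed(81)
  cds <- c(a = randomDnaCds(150))
  cds["b"] <- evolveSequence(cds[["a"]], 0.05)$child
  anc2 <- evolveSequence(cds[["a"]], 1.2)$child
  cds["c"] <- evolveSequence(anc2, 0.05)$child
  cds["d"] <- evolveSequence(anc2, 0.08)$child
  tr <- buildGeneTree(cds, B = 100)
  truth <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth))[1], 0)
  ## the central bipartition is overwhelmingly supported
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
  expect_error(buildGeneTree(cds[1:2]), "at least 3")
})

test_that("rooting uses the outgroup clade, else midpoint", {
  tr <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,o1:1):1);")
  r1 <- rootGeneTree(tr, "o1")
  expect_equal(attr(r1, "rooting"), "outgroup")
  kids <- r1$edge[r1$edge[, 1] == ape::Ntip(r1) + 1, 2]
  expect_true(any(kids <= ape::Ntip(r1) & r1$tip.label[kids] == "o1"))
  ## interleaved outgroup genes: not a clade on any rooting -> midpoint
  tr2 <- ape::read.tree(text = "((o1:1,a1:1):1,(o2:1,b1:1):1);")
  r2 <- rootGeneTree(tr2, c("o1", "o2"))
  expect_equal(attr(r2, "rooting"), "midpoint")
  r3 <- rootGeneTree(tr2, character(0))
  expect_equal(attr(r3, "rooting"), "midpoint")
})

test_that("node classification reproduces by-hand reconciliations", {
  sp <- ape::read.tree(text = "(A:1,B:1);")
  ## ((a1,b1),(a2,b2)): root duplication, both children speciation
  g1 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  c1 <- classifyNodes(g1, sp, gs4)
  expect_equal(sort(c1$label), c("duplication", "speciation", "speciation"))
  root1 <- ape::Ntip(g1) + 1L
  expect_equal(c1$label[c1$node == root1], "duplication")
  ## ((a1,a2),b1): cherry duplication, root speciation
  g2 <- ape::read.tree(text = "((a1:1,a2:1):1,b1:1);")
  c2 <- classifyNodes(g2, sp, gs4)
  expect_equal(c2$label[c2$node == ape::Ntip(g2) + 1L], "speciation")
  expect_equal(c2$label[c2$node != ape::Ntip(g2) + 1L], "duplication")
  ## species tree ((A,B),C), gene tree ((a1,c1),b1): root dubious
  sp3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  g3 <- ape::read.tree(text = "((a1:1,c1:1):1,b1:1);")
  c3 <- classifyNodes(g3, sp3, gs4)
  expect_equal(c3$label[c3$node == ape::Ntip(g3) + 1L], "dubious")
  expect_equal(c3$label[c3$node != ape::Ntip(g3) + 1L], "speciation")
  ## unknown species errors with the gene name
  expect_error(classifyNodes(g3, sp, gs4), "c1")
})

test_that("congruent single-copy trees contain only speciation nodes", {
  sp <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,O:3);")
  g <- ape::read.tree(text = "(((a1:1,b1:1):1,c1:2):1,o1:3);")
  cl <- classifyNodes(g, sp, gs4)
  expect_true(all(cl$label == "speciation"))
})

test_that("anchors trace to the correct species-tree branch interval", {
  sp <- ape::read.tree(text = "((A:1,D:1):1,O:2);")
  gsp <- c(a1 = "A", a2 = "A", d1 = "D", d2 = "D", o1 = "O")
  g <- ape::read.tree(text = "(((a1:1,d1:1):1,(a2:1,d2:1):1):1,o1:3);")
  g$node.label <- c("", "95", "88", "71")
  cl <- classifyNodes(g, sp, gsp)
  p <- placeAnchor("a1", "a2", g, cl, sp)
  expect_true(p$placed)
  expect_equal(p$lower_id, "A|D")
  expect_equal(p$upper_id, "A|D|O")
  expect_equal(p$n_branches, 1L)
  expect_equal(p$assigned_branch, "A|D")
  expect_equal(p$support, 95)
  ## a cross-species pair coalescing at a speciation node stays unplaced
  p2 <- placeAnchor("a1", "d1", g, cl, sp)
  expect_false(p2$placed)
  expect_match(p2$reason, "speciation")
  ## genes absent from the tree are reported unplaced with a reason
  p3 <- placeAnchor("a1", "zz", g, cl, sp)
  expect_false(p3$placed)
})

test_that("root-open intervals are reported unbounded, not forced to a branch", {
  sp <- ape::read.tree(text = "(A:1,B:1);")
  g <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  cl <- classifyNodes(g, sp, gs4)
  ## the a1/a2 coalescent IS the root duplication: no speciation ancestor
  p <- placeAnchor("a1", "a2", g, cl, sp)
  expect_true(p$placed)
  expect_true(is.na(p$upper_id))
  expect_true(is.na(p$assigned_branch))
})

test_that("per-branch counts respect thresholds and monotonicity", {
  pl <- data.frame(
    family = c("f1", "f1", "f2"),
    gene_a = c("a1", "a3", "a5"), gene_b = c("a2", "a4", "a6"),
    placed = TRUE, reason = "single-branch interval",
    lower_id = "A|B", upper_id = "A|B|O", n_branches = 1L,
    assigned_branch = "A|B", support = c(90, 85, 40),
    n_dubious_crossed = 0L, stringsAsFactors = FALSE)
  cnt <- countEventsPerBranch(pl, c(50, 80))
  at80 <- cnt[cnt$threshold == 80, ]
  at50 <- cnt[cnt$threshold == 50, ]
  expect_equal(at80$n_anchor_pairs, 2L)
  expect_equal(at80$n_families, 1L)
  expect_equal(at50$n_anchor_pairs, 2L)
  expect_true(all(at80$n_anchor_pairs <= at50$n_anchor_pairs))
  ## no qualifying placements -> empty counts
  pl0 <- pl; pl0$assigned_branch <- NA_character_
  expect_equal(nrow(countEventsPerBranch(pl0)), 0L)
})

test_that("the full placement pipeline recovers a stem WGD", {
  sim <- simStemWgd(seed = 606, nFamilies = 30)
  fams <- buildFamilies(sim$homology, 1e-5)
  gsp <- geneSpeciesMap(sim)
  anch <- trueAnchors(sim$truth)
  anch$ks <- ksPairwise(sim$cds, anch[, c("gene_a", "gene_b")])$ks
  flt <- filterFamiliesForPlacement(fams, anch, gsp, "O")
  set.seed(1)
  pl <- placeAnchors(flt, sim$cds, sim$speciesTree, gsp, "O", B = 100)
  placed <- pl[pl$placed & !is.na(pl$assigned_branch), ]
  expect_gt(nrow(placed), 0)
  expect_gt(mean(placed$assigned_branch == "A|B|C"), 0.9)
})
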