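test_that("families are connected components above the cutoff", {
  e <- data.frame(gene_a = c("a", "b", "x"), gene_b = c("b", "c", "y"),
                  evalue = c(1e-20, 1e-20, 1e-5))
  fams <- buildFamilies(e, 1e-10)
  expect_length(fams, 1L)
  expect_equal(fams[[1L]], c("a", "b", "c"))
  expect_length(buildFamilies(e[0, ], 1e-10), 0L)
})

test_that("components agree with a brute-force oracle on random graphs", {
  set.seed(21)
  for (i in 1:10) {
    genes <- sprintf("g%02d", 1:50)
    e <- data.frame(gene_a = sample(genes, 60, TRUE),
                    gene_b = sample(genes, 60, TRUE))
    e <- e[e$gene_a != e$gene_b, ]
    fams <- buildFamilies(e, 1)
    oracle <- oracleComponents(e)
    oracle <- oracle[lengths(oracle) >= 2]
    expect_equal(canonicalPartition(unname(fams)), canonicalPartition(oracle))
  }
})

test_that("subfamily splitting enforces the all-pairs Ks ceiling", {
  m <- matrix(c(0, 0.5, 6, 0.5, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  subs <- splitSubfamilies(c("a", "b", "c"), m, maxKs = 5)
  expect_equal(canonicalPartition(subs),
               canonicalPartition(list(c("a", "b"), "c")))
  ## all pairs under the ceiling: one subfamily
  m2 <- m; m2[m2 == 6] <- 3
  expect_length(splitSubfamilies(c("a", "b", "c"), m2, 5), 1L)
})

test_that("subfamily splitting matches greedy complete-linkage merging", {
  set.seed(5)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    ids <- letters[1:n]
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    v <- runif(n * (n - 1) / 2, 0, 10)
    m[upper.tri(m)] <- v
    m <- m + t(m)
    got <- splitSubfamilies(ids, m, maxKs = 5)
    want <- oracleCompleteLinkage(ids, m, maxKs = 5)
    ## both must satisfy the all-pairs condition ...
    for (cl in got)
      if (length(cl) > 1) expect_lte(max(m[cl, cl]), 5)
    ## ... and agree
    expect_equal(canonicalPartition(got), canonicalPartition(want))
  }
})

test_that("UPGMA subfamily trees recover ultrametric truth", {
  ## forced topology ((a,b),c)
  m <- matrix(c(0, 0.2, 1, 0.2, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- subfamilyTree(m)
  expect_equal(sort(tr$labels[-tr$merge[1, ]]), c("a", "b"))
  ## random ultrametric matrices: recovered tree is the true one
  set.seed(31)
  for (i in 1:10) {
    phy <- ape::rcoal(6)
    phy$tip.label <- letters[1:6]
    d <- ape::cophenetic.phylo(phy)
    hc <- subfamilyTree(d)
    rec <- ape::as.phylo(hc)
    expect_equal(ape::dist.topo(ape::unroot(rec), ape::unroot(phy))[1], 0)
  }
  ## 2-member subfamily: single merge at the pairwise Ks
  m2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- subfamilyTree(m2)
  expect_equal(tr2$height, 0.8)
})

test_that("node weighting conserves one unit of mass per duplication event", {
  ## ((a,b),c): node (a,b) gets weight 1; the root splits 1/2 + 1/2
  m <- matrix(c(0, 0.2, 1, 0.2, 0, 1.2, 1, 1.2, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- subfamilyTree(m)
  w <- weightNodeKs(tr, m, "sf")
  expect_equal(nrow(w), 3L)
  expect_equal(w$weight[w$gene_a == "a" & w$gene_b == "b"], 1)
  expect_equal(sort(w$weight), c(0.5, 0.5, 1))
  ## n = 5: 10 pairwise entries carrying total mass 4
  set.seed(8)
  ids <- letters[1:5]
  m5 <- matrix(0, 5, 5, dimnames = list(ids, ids))
  m5[upper.tri(m5)] <- runif(10, 0.1, 2)
  m5 <- m5 + t(m5)
  w5 <- weightNodeKs(subfamilyTree(m5), m5, "sf5")
  expect_equal(nrow(w5), 10L)
  expect_equal(sum(w5$weight), 4)
  ## random 7-leaf trees: per-node mass exactly 1, global mass n - 1
  for (i in 1:10) {
    ids <- letters[1:7]
    mm <- matrix(0, 7, 7, dimnames = list(ids, ids))
    mm[upper.tri(mm)] <- runif(21, 0.1, 3)
    mm <- mm + t(mm)
    ww <- weightNodeKs(subfamilyTree(mm), mm, "r")
    perNode <- tapply(ww$weight, ww$node_id, sum)
    expect_equal(as.numeric(perNode), rep(1, 6), tolerance = 1e-12)
    expect_equal(sum(ww$weight), 6, tolerance = 1e-12)
  }
})

test_that("the weighted distribution ignores duplicated homology rows", {
  sim <- simOneWgd(seed = 303, nFamilies = 40)
  hom <- speciesHomology(sim, "A")
  d1 <- paranomeKs(sim$cds, hom)
  d2 <- paranomeKs(sim$cds, rbind(hom, hom[rep(1:5, 3), ]))
  expect_equal(ksEntries(d1), ksEntries(d2))
})

test_that("window selection uses a closed interval", {
  e <- data.frame(gene_a = "a", gene_b = "b", ks = c(0.6, 1.4, 1.41, 0.59),
                  weight = 1)
  out <- selectWindow(e, 0.6, 1.4)
  expect_equal(out$ks, c(0.6, 1.4))
  expect_equal(nrow(selectWindow(e[0, ], 0.6, 1.4)), 0L)
  ## brute-force agreement on a random sample
  set.seed(2)
  e2 <- data.frame(gene_a = "a", gene_b = "b", ks = runif(1000, 0, 3), weight = 1)
  expect_equal(nrow(selectWindow(e2, 0.6, 1.4)),
               sum(e2$ks >= 0.6 & e2$ks <= 1.4))
})

test_that("KDE peak finds modes of known distributions", {
  expect_error(kdePeak(rep(1.3, 5)), "at least 10")
  ## degenerate sample: peak at the common value, CI width 0
  p <- kdePeak(rep(1.3, 50))
  expect_equal(p$peak, 1.3)
  set.seed(4)
  ci <- bootstrapPeakCi(rep(1.3, 50), B = 100)
  expect_equal(ci$lo, 1.3)
  expect_equal(ci$hi, 1.3)
  ## unimodal normal
  set.seed(14)
  x <- rnorm(500, 1.0, 0.2)
  pk <- kdePeak(x)
  expect_lt(abs(pk$peak - 1.0), 0.05)
  ci <- bootstrapPeakCi(x, B = 200)
  expect_lte(ci$lo, 1.0)
  expect_gte(ci$hi, 1.0)
  ## mixture: global peak near 0.9, secondary mode near 3.0 reported
  set.seed(15)
  x2 <- c(rnorm(700, 0.9, 0.15), rnorm(300, 3.0, 0.3))
  pk2 <- kdePeak(x2)
  expect_lt(abs(pk2$peak - 0.9), 0.1)
  expect_true(any(abs(pk2$modes$location - 3.0) < 0.2))
})
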