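test_that("c-score uses the larger of the two genes' best bit-scores", {
  e <- data.frame(gene_a = c("a", "a", "b"),
                  gene_b = c("x", "b", "y"),
                  bitscore = c(200, 90, 150),
                  evalue = 1e-50)
  out <- cscoreFilter(e, 0.5)
  ## cscore(a,b) = 90 / max(200, 150) = 0.45 -> removed
  expect_false(any(out$gene_a == "a" & out$gene_b == "b"))
  ## a gene's best hit that is also the partner's best hit has cscore 1
  expect_true(any(out$bitscore == 200))
})

test_that("c-score filter agrees with a brute-force filter", {
  set.seed(77)
  for (i in 1:10) {
    genes <- sprintf("g%d", 1:12)
    e <- data.frame(gene_a = sample(genes, 40, TRUE),
                    gene_b = sample(genes, 40, TRUE),
                    bitscore = runif(40, 10, 300), evalue = 1e-30)
    e <- e[e$gene_a != e$gene_b, ]
    e <- e[!duplicated(e[, 1:2]), ]
    got <- cscoreFilter(e, 0.5)
    best <- sapply(genes, function(g)
      max(c(-Inf, e$bitscore[e$gene_a == g | e$gene_b == g])))
    keep <- e$bitscore / pmax(best[e$gene_a], best[e$gene_b]) >= 0.5
    expect_equal(nrow(got), sum(keep))
  }
})

test_that("perfect diagonals chain into single segments", {
  m <- data.frame(rank_a = 1:3, rank_b = 4:6)
  segs <- chainMatches(m, minAnchors = 3)
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$direction, "forward")
  expect_equal(nrow(segs[[1]]$anchors), 3L)
  ## anti-diagonal
  m2 <- data.frame(rank_a = 1:3, rank_b = 6:4)
  segs2 <- chainMatches(m2, minAnchors = 3)
  expect_length(segs2, 1L)
  expect_equal(segs2[[1]]$direction, "inverted")
})

test_that("chained segments are strictly monotone in both coordinates", {
  set.seed(99)
  for (i in 1:20) {
    m <- data.frame(rank_a = sample(0:30, 20, TRUE),
                    rank_b = sample(0:30, 20, TRUE))
    m <- m[!duplicated(m), ]
    segs <- chainMatches(m, minAnchors = 2)
    for (s in segs) {
      a <- s$anchors[order(s$anchors$rank_a), ]
      expect_true(all(diff(a$rank_a) > 0))
      d <- diff(a$rank_b)
      expect_true(all(d > 0) || all(d < 0))
    }
  }
})

test_that("best chain equals exhaustive enumeration on small instances", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    m <- data.frame(rank_a = sample(0:7, n, TRUE), rank_b = sample(0:7, n, TRUE))
    m <- m[!duplicated(m), ]
    segs <- chainMatches(m, maxGap = 25, minAnchors = 1)
    expect_equal(max(vapply(segs, `[[`, numeric(1), "score")),
                 oracleBestChainScore(m, maxGap = 25))
  }
})

test_that("raising the anchor floor never yields more segments", {
  sim <- simOneWgd(seed = 404, nFamilies = 100, retention = 0.6)
  hom <- speciesHomology(sim, "A")
  n5 <- nrow(segmentTable(collinearSegments(sim$genomes$A, edges = hom, minAnchors = 5)))
  n10 <- nrow(segmentTable(collinearSegments(sim$genomes$A, edges = hom, minAnchors = 10)))
  n15 <- nrow(segmentTable(collinearSegments(sim$genomes$A, edges = hom, minAnchors = 15)))
  expect_lte(n10, n5)
  expect_lte(n15, n10)
})

test_that("anchor sets are symmetric under swapping the two genomes", {
  sim <- simStemWgd(seed = 42, nFamilies = 30, retention = 1)
  sab <- collinearSegments(sim$genomes$A, sim$genomes$B, sim$homology, minAnchors = 5)
  sba <- collinearSegments(sim$genomes$B, sim$genomes$A, sim$homology, minAnchors = 5)
  pab <- with(anchorPairs(sab), sort(paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b))))
  pba <- with(anchorPairs(sba), sort(paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b))))
  expect_equal(pab, pba)
})

test_that("overlapping rank intervals merge; bookended ones do not", {
  seg <- data.frame(segment_id = c("s1", "s2", "s3"),
                    scaffold_a = "sc1", scaffold_b = c("x", "y", "z"),
                    direction = "forward", n_anchors = 5, score = 50,
                    a_start = c(0L, 4L, 11L), a_end = c(5L, 9L, 15L),
                    b_start = 0L, b_end = 5L)
  anch <- data.frame(segment_id = character(0), gene_a = character(0),
                     gene_b = character(0), rank_a = integer(0),
                     rank_b = integer(0))
  ss <- new("CollinearSegmentSet", segments = seg, anchors = anch, self = FALSE)
  mg <- mergeSegments(ss, side = "a")
  expect_equal(nrow(mg$regions), 2L)
  expect_equal(mg$regions$start, c(0L, 11L))
  expect_equal(mg$regions$end, c(9L, 15L))
})

test_that("region union matches brute-force interval union on random input", {
  set.seed(55)
  for (i in 1:10) {
    n <- 50
    st <- sample(0:200, n, TRUE)
    en <- st + sample(0:20, n, TRUE)
    seg <- data.frame(segment_id = sprintf("s%d", 1:n), scaffold_a = "sc",
                      scaffold_b = sprintf("o%d", 1:n), direction = "forward",
                      n_anchors = 5, score = 1, a_start = st, a_end = en,
                      b_start = 0L, b_end = 1L)
    ss <- new("CollinearSegmentSet", segments = seg,
              anchors = data.frame(segment_id = character(0),
                                   gene_a = character(0), gene_b = character(0),
                                   rank_a = integer(0), rank_b = integer(0)),
              self = FALSE)
    mg <- mergeSegments(ss, side = "a")
    ## brute-force union under the shared-rank relation: a sweep that starts
    ## a new region when the next interval begins strictly after the current
    ## region's end (bookended intervals stay separate)
    o <- order(st, en)
    nReg <- 0L; curEnd <- -1L
    for (k in o) {
      if (st[k] > curEnd) { nReg <- nReg + 1L; curEnd <- en[k] }
      else curEnd <- max(curEnd, en[k])
    }
    expect_equal(nrow(mg$regions), nReg)
  }
})

test_that("raw depth counts covering segment intervals", {
  seg <- data.frame(segment_id = c("s1", "s2"), scaffold_a = "sc1",
                    scaffold_b = c("x", "y"), direction = "forward",
                    n_anchors = 5, score = 50,
                    a_start = c(0L, 10L), a_end = c(20L, 30L),
                    b_start = 0L, b_end = 20L)
  ss <- new("CollinearSegmentSet", segments = seg,
            anchors = data.frame(segment_id = character(0),
                                 gene_a = character(0), gene_b = character(0),
                                 rank_a = integer(0), rank_b = integer(0)),
            self = FALSE)
  d <- duplicationDepth(ss, "sc1", scaffoldLength = 40, side = "a")
  expect_equal(d[1], 1L)          # rank 0
  expect_equal(d[15], 2L)         # rank 14, overlap zone 10..20
  expect_equal(d[40], 0L)         # rank 39, uncovered
  ## brute-force recomputation
  brute <- integer(40)
  for (r in 0:39) brute[r + 1] <- sum(seg$a_start <= r & seg$a_end >= r)
  expect_equal(d, brute)
  ## the profile convention adds the reference region itself
  dp <- duplicationDepth(ss, "sc1", scaffoldLength = 40, includeSelf = TRUE,
                         side = "a")
  expect_equal(dp[15], 3L)
  expect_equal(dp[40], 0L)
})

test_that("one region hit by four disjoint partner segments reports 4:1", {
  seg <- data.frame(segment_id = sprintf("s%d", 1:4),
                    scaffold_a = sprintf("a%d", 1:4), scaffold_b = "b1",
                    direction = "forward", n_anchors = 5, score = 50,
                    a_start = 0L, a_end = 9L,
                    b_start = 0L, b_end = 9L)
  ss <- new("CollinearSegmentSet", segments = seg,
            anchors = data.frame(segment_id = character(0),
                                 gene_a = character(0), gene_b = character(0),
                                 rank_a = integer(0), rank_b = integer(0)),
            self = FALSE)
  ps <- patternSummary(ss)
  expect_equal(ps$pattern, "4:1")
})
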