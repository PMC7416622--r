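# Independent brute-force oracles. These deliberately avoid the package's
# lookup tables and dynamic programs: sites and pathway averages are computed
# by direct enumeration/recursion, chains by exhaustive search, components and
# RBH by double loops.

.oracleCode <- as.list(Biostrings::GENETIC_CODE)
.oracleBases <- c("A", "C", "G", "T")

oracleAa <- function(codon) .oracleCode[[codon]]
oracleIsStop <- function(codon) oracleAa(codon) == "*"

.oracleSiteCache <- new.env(parent = emptyenv())
oracleSitesCodon <- function(codon) {
  hit <- .oracleSiteCache[[codon]]
  if (!is.null(hit)) return(hit)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(.oracleBases, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (!oracleIsStop(alt) && oracleAa(alt) == oracleAa(codon)) s <- s + 1 / 3
    }
  }
  .oracleSiteCache[[codon]] <- s
  s
}

# recursively enumerate every stop-free mutational pathway between two codons,
# returning the synonymous step count of each pathway
oraclePathsSyn <- function(cur, target) {
  if (cur == target) return(0)
  out <- numeric(0)
  for (p in 1:3) {
    if (substr(cur, p, p) == substr(target, p, p)) next
    nxt <- cur
    substr(nxt, p, p) <- substr(target, p, p)
    if (oracleIsStop(nxt)) next
    step <- as.numeric(oracleAa(nxt) == oracleAa(cur))
    out <- c(out, step + oraclePathsSyn(nxt, target))
  }
  out
}

oracleKsPair <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  stopifnot(length(ca) == length(cb))
  # drop a trailing stop codon, mirroring CDS conventions
  if (oracleIsStop(ca[length(ca)]) && oracleIsStop(cb[length(cb)])) {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  Sd <- 0; Nd <- 0; Sa <- 0; Sb <- 0; n <- 0
  for (i in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    nd <- sum(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    if (nd > 0) {
      syns <- oraclePathsSyn(ca[i], cb[i])
      if (!length(syns)) next  # every pathway blocked: skip the codon pair
      Sd <- Sd + mean(syns)
      Nd <- Nd + (nd - mean(syns))
    }
    Sa <- Sa + oracleSitesCodon(ca[i])
    Sb <- Sb + oracleSitesCodon(cb[i])
    n <- n + 1
  }
  Ssites <- (Sa + Sb) / 2
  Nsites <- 3 * n - Ssites
  pS <- Sd / Ssites
  pN <- Nd / Nsites
  jc <- function(p) if (1 - 4 * p / 3 <= 0) Inf else -0.75 * log(1 - 4 * p / 3)
  list(ks = jc(pS), ka = jc(pN), pS = pS, pN = pN,
       S_sites = Ssites, N_sites = Nsites, Sd = Sd, Nd = Nd)
}

# exhaustive best-chain search: enumerates every valid chain (both
# directions) by depth-first extension and returns the maximum score
oracleBestChainScore <- function(matches, maxGap = 25, matchScore = 10,
                                 gapPenalty = -1) {
  n <- nrow(matches)
  if (n == 0) return(-Inf)
  ra <- matches$rank_a; rb <- matches$rank_b
  best <- matchScore  # any single match is a chain
  extend <- function(last, score, dir) {
    best <<- max(best, score)
    for (q in seq_len(n)) {
      da <- ra[q] - ra[last]
      db <- (rb[q] - rb[last]) * dir
      if (da > 0 && da <= maxGap && db > 0 && db <= maxGap) {
        extend(q, score + matchScore + gapPenalty * ((da - 1) + (db - 1)), dir)
      }
    }
  }
  for (s in seq_len(n)) for (dir in c(1, -1)) extend(s, matchScore, dir)
  best
}

oracleRbh <- function(ab, ba, cutoff = 1e-5) {
  ab <- ab[ab$evalue <= cutoff, , drop = FALSE]
  ba <- ba[ba$evalue <= cutoff, , drop = FALSE]
  bestOf <- function(e, g) {
    rows <- e[e$gene_a == g, , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    rows <- rows[order(-rows$bitscore, rows$evalue, rows$gene_b), , drop = FALSE]
    rows$gene_b[1]
  }
  pairs <- list()
  for (g in unique(ab$gene_a)) {
    h <- bestOf(ab, g)
    if (!is.na(h) && identical(bestOf(ba, h), g))
      pairs[[length(pairs) + 1]] <- data.frame(gene_a = g, gene_b = h,
                                               stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0))
  out[order(out$gene_a), , drop = FALSE]
}

# connected components by repeated neighbourhood expansion
oracleComponents <- function(edges) {
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  comp <- list()
  seen <- character(0)
  for (g in genes) {
    if (g %in% seen) next
    grp <- g
    repeat {
      nb <- unique(c(edges$gene_b[edges$gene_a %in% grp],
                     edges$gene_a[edges$gene_b %in% grp]))
      new <- setdiff(nb, grp)
      if (!length(new)) break
      grp <- c(grp, new)
    }
    comp[[length(comp) + 1]] <- sort(grp)
    seen <- c(seen, grp)
  }
  comp[order(vapply(comp, `[`, character(1), 1))]
}

# greedy complete-linkage agglomeration: keep merging the closest pair of
# clusters (by maximum pairwise distance) while the linkage stays <= maxKs
oracleCompleteLinkage <- function(members, ksMatrix, maxKs) {
  cl <- as.list(members)
  repeat {
    bestD <- Inf; bi <- 0; bj <- 0
    if (length(cl) < 2) break
    for (i in seq_len(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      d <- max(ksMatrix[cl[[i]], cl[[j]]])
      if (!is.finite(d)) d <- Inf
      if (d < bestD) { bestD <- d; bi <- i; bj <- j }
    }
    if (bestD > maxKs) break
    cl[[bi]] <- sort(c(cl[[bi]], cl[[bj]]))
    cl[[bj]] <- NULL
  }
  lapply(cl, sort)
}

canonicalPartition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, `[`, character(1), 1))]
}

randomDnaCds <- function(nCodons) {
  nonStop <- names(.oracleCode)[unlist(.oracleCode) != "*"]
  paste(sample(nonStop, nCodons, replace = TRUE), collapse = "")
}
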