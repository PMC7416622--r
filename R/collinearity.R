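## Co-linear segment (anchor) detection by dynamic-programming chaining of
## gene-order match points, region merging, duplication-depth profiles and
## cross-genome multiplicity patterns.

#' c-score filter for homology edges
#'
#' The c-score of an edge (a,b) is its bit-score divided by the larger of the
#' best bit-scores involving a or b; weak matches with c-score below the
#' cutoff are removed. Retains ties with the best hit by construction (the
#' mutual best hit of two genes always has c-score 1).
#'
#' @param edges data.frame with \code{gene_a}, \code{gene_b},
#'   \code{bitscore}.
#' @param minCscore minimum retained c-score (default 0.5).
#' @return \code{edges} with a \code{cscore} column added and weak rows
#'   removed.
#' @export
cscoreFilter <- function(edges, minCscore = 0.5) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) { edges$cscore <- numeric(0); return(edges) }
  best <- tapply(rep(edges$bitscore, 2L), c(edges$gene_a, edges$gene_b), max)
  edges$cscore <- edges$bitscore /
    pmax(best[edges$gene_a], best[edges$gene_b])
  out <- edges[edges$cscore >= minCscore, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-order match points between two genomes
#'
#' Joins homology edges onto gene ranks to produce the dots of a synteny dot
#' plot. For a self-comparison the identity diagonal (a gene matched to
#' itself) is masked and each unordered pair appears once (same-scaffold
#' matches oriented with \code{rank_a < rank_b}; scaffold pairs oriented by
#' scaffold id).
#'
#' @param genomeA,genomeB \linkS4class{SpeciesGenome} objects;
#'   omit/\code{NULL} \code{genomeB} for a self-comparison.
#' @param edges homology edges (\code{gene_a}, \code{gene_b}).
#' @return data.frame: \code{scaffold_a}, \code{scaffold_b}, \code{gene_a},
#'   \code{gene_b}, \code{rank_a}, \code{rank_b}.
#' @export
matchPoints <- function(genomeA, genomeB = NULL, edges) {
  self <- is.null(genomeB)
  if (self) genomeB <- genomeA
  ga <- geneTable(genomeA); gb <- geneTable(genomeB)
  e <- as.data.frame(edges, stringsAsFactors = FALSE)[, c("gene_a", "gene_b")]
  ## orient edges so gene_a is in genome A, gene_b in genome B
  inA1 <- e$gene_a %in% ga$gene_id & e$gene_b %in% gb$gene_id
  inA2 <- e$gene_b %in% ga$gene_id & e$gene_a %in% gb$gene_id
  straight <- e[inA1, , drop = FALSE]
  flipped <- e[inA2 & !inA1, c("gene_b", "gene_a"), drop = FALSE]
  names(flipped) <- c("gene_a", "gene_b")
  e <- rbind(straight, flipped)
  if (self) e <- e[e$gene_a != e$gene_b, , drop = FALSE]
  if (!nrow(e))
    return(data.frame(scaffold_a = character(0), scaffold_b = character(0),
                      gene_a = character(0), gene_b = character(0),
                      rank_a = integer(0), rank_b = integer(0)))
  ia <- match(e$gene_a, ga$gene_id); ib <- match(e$gene_b, gb$gene_id)
  mp <- data.frame(scaffold_a = ga$scaffold[ia], scaffold_b = gb$scaffold[ib],
                   gene_a = e$gene_a, gene_b = e$gene_b,
                   rank_a = ga$rank[ia], rank_b = gb$rank[ib],
                   stringsAsFactors = FALSE)
  if (self) {
    ## canonical orientation: one row per unordered pair
    flip <- mp$scaffold_a > mp$scaffold_b |
      (mp$scaffold_a == mp$scaffold_b & mp$rank_a > mp$rank_b)
    mp[flip, c("scaffold_a", "scaffold_b", "gene_a", "gene_b",
               "rank_a", "rank_b")] <-
      mp[flip, c("scaffold_b", "scaffold_a", "gene_b", "gene_a",
                 "rank_b", "rank_a")]
    mp <- mp[!duplicated(mp[, c("gene_a", "gene_b")]), , drop = FALSE]
  }
  mp <- mp[!duplicated(mp), , drop = FALSE]
  rownames(mp) <- NULL
  mp
}

## DP over one direction; matches must be deduplicated on (rank_a, rank_b).
## Returns list(score, chain indices) of the maximal-scoring chain, or NULL.
.bestChainDir <- function(ra, rb, dir, maxGap, matchScore, gapPenalty) {
  n <- length(ra)
  o <- order(ra, rb * dir)
  ra <- ra[o]; rb <- rb[o]
  sc <- rep(matchScore, n)
  prev <- rep(0L, n)
  for (q in seq_len(n)) {
    da <- ra[q] - ra
    db <- (rb[q] - rb) * dir
    okp <- which(da > 0 & da <= maxGap & db > 0 & db <= maxGap)
    if (length(okp)) {
      cand <- sc[okp] + matchScore + gapPenalty * ((da[okp] - 1) + (db[okp] - 1))
      j <- which.max(cand)
      if (cand[j] > sc[q]) { sc[q] <- cand[j]; prev[q] <- okp[j] }
    }
  }
  e <- which.max(sc)
  chain <- integer(0)
  while (e != 0L) { chain <- c(e, chain); e <- prev[e] }
  list(score = max(sc), idx = o[chain])
}

#' Chain match points into co-linear segments
#'
#' Sparse dynamic program over match points of one scaffold pair: a chain may
#' extend from match p to q iff both rank gaps are positive and at most
#' \code{maxGap}, with a consistent direction (forward: rank_b increasing;
#' inverted: decreasing). Chain score is \code{matchScore} per anchor plus
#' \code{gapPenalty} per skipped rank on either axis. Segments are reported
#' greedily: the maximal-scoring chain is extracted, its matches are retired,
#' and the program repeats until the best remaining chain falls below
#' \code{minAnchors} anchors; each match thus belongs to at most one segment.
#' Defaults (gap 25, match +10, gap penalty -1) are chosen to recover
#' segments of five or more anchors through moderate fractionation.
#'
#' @param matches data.frame with \code{rank_a}, \code{rank_b} (and
#'   optionally gene ids) for a single scaffold pair.
#' @param maxGap maximum rank gap bridged between consecutive anchors.
#' @param matchScore score per anchor.
#' @param gapPenalty (negative) penalty per skipped rank.
#' @param minAnchors minimum anchors per reported segment.
#' @return List of segments, each a list with \code{direction},
#'   \code{score} and \code{anchors} (the matching rows, ordered along the
#'   chain).
#' @export
chainMatches <- function(matches, maxGap = 25, matchScore = 10,
                         gapPenalty = -1, minAnchors = 5) {
  matches <- as.data.frame(matches, stringsAsFactors = FALSE)
  matches <- matches[!duplicated(matches[, c("rank_a", "rank_b")]), , drop = FALSE]
  rownames(matches) <- NULL
  segs <- list()
  unused <- rep(TRUE, nrow(matches))
  while (sum(unused) >= max(1L, minAnchors)) {
    live <- which(unused)
    ra <- matches$rank_a[live]; rb <- matches$rank_b[live]
    fwd <- .bestChainDir(ra, rb, 1L, maxGap, matchScore, gapPenalty)
    inv <- .bestChainDir(ra, rb, -1L, maxGap, matchScore, gapPenalty)
    pick <- if (inv$score > fwd$score ||
                (inv$score == fwd$score && length(inv$idx) > length(fwd$idx)))
      inv else fwd
    dir <- "forward"
    if (length(pick$idx) > 1L) {
      rbs <- matches$rank_b[live[pick$idx]]
      dir <- if (rbs[2L] > rbs[1L]) "forward" else "inverted"
    }
    if (length(pick$idx) < minAnchors) break
    rows <- live[pick$idx]
    segs[[length(segs) + 1L]] <- list(direction = dir, score = pick$score,
                                      anchors = matches[rows, , drop = FALSE])
    unused[rows] <- FALSE
  }
  segs
}

#' Detect co-linear segments between (or within) genomes
#'
#' Runs \code{\link{chainMatches}} on every scaffold pair with enough match
#' points and assembles the results into a \linkS4class{CollinearSegmentSet}.
#'
#' @inheritParams matchPoints
#' @inheritParams chainMatches
#' @return A \linkS4class{CollinearSegmentSet}.
#' @export
collinearSegments <- function(genomeA, genomeB = NULL, edges,
                              minAnchors = 5, maxGap = 25, matchScore = 10,
                              gapPenalty = -1) {
  self <- is.null(genomeB)
  mp <- matchPoints(genomeA, genomeB, edges)
  segRows <- list(); anchRows <- list()
  if (nrow(mp)) {
    key <- paste(mp$scaffold_a, mp$scaffold_b, sep = "\r")
    for (grp in split(mp, key)) {
      if (nrow(grp) < minAnchors) next
      segs <- chainMatches(grp, maxGap, matchScore, gapPenalty, minAnchors)
      for (s in segs) {
        a <- s$anchors
        segRows[[length(segRows) + 1L]] <- data.frame(
          scaffold_a = a$scaffold_a[1L], scaffold_b = a$scaffold_b[1L],
          direction = s$direction, n_anchors = nrow(a), score = s$score,
          a_start = min(a$rank_a), a_end = max(a$rank_a),
          b_start = min(a$rank_b), b_end = max(a$rank_b),
          stringsAsFactors = FALSE)
        anchRows[[length(anchRows) + 1L]] <-
          a[, c("gene_a", "gene_b", "rank_a", "rank_b")]
      }
    }
  }
  if (!length(segRows)) {
    return(new("CollinearSegmentSet",
               segments = data.frame(segment_id = character(0),
                                     scaffold_a = character(0),
                                     scaffold_b = character(0),
                                     direction = character(0),
                                     n_anchors = integer(0), score = numeric(0),
                                     a_start = integer(0), a_end = integer(0),
                                     b_start = integer(0), b_end = integer(0)),
               anchors = data.frame(segment_id = character(0),
                                    gene_a = character(0), gene_b = character(0),
                                    rank_a = integer(0), rank_b = integer(0)),
               self = self))
  }
  seg <- do.call(rbind, segRows)
  o <- order(seg$scaffold_a, seg$scaffold_b, seg$a_start, seg$b_start)
  seg <- seg[o, , drop = FALSE]
  seg <- cbind(segment_id = sprintf("seg%05d", seq_len(nrow(seg))), seg,
               stringsAsFactors = FALSE)
  anch <- do.call(rbind, lapply(seq_along(o), function(k) {
    a <- anchRows[[o[k]]]
    a <- a[order(a$rank_a), , drop = FALSE]
    cbind(segment_id = seg$segment_id[k], a, stringsAsFactors = FALSE)
  }))
  rownames(seg) <- rownames(anch) <- NULL
  new("CollinearSegmentSet", segments = seg, anchors = anch, self = self)
}

## closed rank intervals contributed by segments to each genome side
.segmentIntervals <- function(segset, side = c("both", "a", "b")) {
  side <- match.arg(side)
  s <- segmentTable(segset)
  out <- list()
  if (side %in% c("both", "a"))
    out$a <- data.frame(segment_id = s$segment_id, side = "a",
                        scaffold = s$scaffold_a, start = s$a_start,
                        end = s$a_end, stringsAsFactors = FALSE)
  if (side %in% c("both", "b"))
    out$b <- data.frame(segment_id = s$segment_id, side = "b",
                        scaffold = s$scaffold_b, start = s$b_start,
                        end = s$b_end, stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge overlapping co-linear segments into broader regions
#'
#' On each scaffold, the closed rank intervals of the contributing segments
#' are unioned into regions whenever they share at least one rank (bookended
#' intervals touching without a shared rank stay separate).
#'
#' @param segset a \linkS4class{CollinearSegmentSet}.
#' @param side which segment side(s) to project onto scaffolds:
#'   \code{"both"} (default; appropriate for self-comparisons), \code{"a"} or
#'   \code{"b"} (cross-genome comparisons, one genome at a time).
#' @return List with \code{regions} (data.frame \code{region_id},
#'   \code{scaffold}, \code{start}, \code{end}, \code{n_segments}) and
#'   \code{members} (data.frame \code{segment_id}, \code{side},
#'   \code{region_id}).
#' @export
mergeSegments <- function(segset, side = c("both", "a", "b")) {
  iv <- .segmentIntervals(segset, match.arg(side))
  if (!nrow(iv)) {
    return(list(regions = data.frame(region_id = character(0),
                                     scaffold = character(0),
                                     start = integer(0), end = integer(0),
                                     n_segments = integer(0)),
                members = data.frame(segment_id = character(0),
                                     side = character(0),
                                     region_id = character(0))))
  }
  regions <- list(); members <- list()
  for (sc in sort(unique(iv$scaffold))) {
    ivs <- iv[iv$scaffold == sc, , drop = FALSE]
    ir <- IRanges::IRanges(start = ivs$start + 1L, end = ivs$end + 1L)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red)
    rid <- sprintf("%s:reg%03d", sc, seq_along(red))
    regions[[sc]] <- data.frame(
      region_id = rid, scaffold = sc,
      start = IRanges::start(red) - 1L, end = IRanges::end(red) - 1L,
      n_segments = as.integer(table(factor(S4Vectors::subjectHits(hit),
                                           levels = seq_along(red)))),
      stringsAsFactors = FALSE)
    members[[sc]] <- data.frame(
      segment_id = ivs$segment_id[S4Vectors::queryHits(hit)],
      side = ivs$side[S4Vectors::queryHits(hit)],
      region_id = rid[S4Vectors::subjectHits(hit)],
      stringsAsFactors = FALSE)
  }
  list(regions = do.call(rbind, c(regions, list(make.row.names = FALSE))),
       members = do.call(rbind, c(members, list(make.row.names = FALSE))))
}

#' Duplication-depth profile of a scaffold
#'
#' The raw depth at rank r is the number of co-linear segment intervals
#' covering r. With \code{includeSelf = TRUE} the reference region itself is
#' counted as one of the stacked co-linear segments wherever any segment
#' covers the position, which is the convention of dot-plot margin profiles:
#' a region retained in four genomic copies is then reported at depth 4 (it
#' is covered by segments to its three sister copies plus itself), directly
#' reflecting the copy multiplicity left by two WGD rounds.
#'
#' @param segset a \linkS4class{CollinearSegmentSet}.
#' @param scaffold scaffold id.
#' @param scaffoldLength number of genes on the scaffold (defaults to the
#'   largest covered rank + 1).
#' @param includeSelf count the reference region as one stacked segment.
#' @param side which segment sides to project (see
#'   \code{\link{mergeSegments}}).
#' @return Integer vector of depths for ranks \code{0:(scaffoldLength-1)}.
#' @export
duplicationDepth <- function(segset, scaffold, scaffoldLength = NULL,
                             includeSelf = FALSE, side = "both") {
  iv <- .segmentIntervals(segset, side)
  iv <- iv[iv$scaffold == scaffold, , drop = FALSE]
  maxEnd <- if (nrow(iv)) max(iv$end) + 1L else 0L
  if (is.null(scaffoldLength)) scaffoldLength <- maxEnd
  depth <- integer(scaffoldLength)
  if (nrow(iv)) {
    cov <- IRanges::coverage(IRanges::IRanges(start = iv$start + 1L,
                                              end = iv$end + 1L),
                             width = scaffoldLength)
    depth <- as.integer(cov)
  }
  if (includeSelf) depth[depth > 0L] <- depth[depth > 0L] + 1L
  depth
}

#' Cross-genome multiplicity pattern of merged regions
#'
#' For each merged region in genome B, counts the distinct genome-A regions
#' aligned to it through co-linear segments (and vice versa), yielding
#' multiplicity claims such as 4:1 (four paralogous A segments over one B
#' region) or 2:2 (a shared WGD retained in both genomes).
#'
#' @param segset a cross-genome \linkS4class{CollinearSegmentSet}.
#' @return List with \code{perRegionB} and \code{perRegionA} (data.frames of
#'   partner-region counts), \code{modalA}, \code{modalB} (modal counts) and
#'   \code{pattern} (string \code{"a:b"}).
#' @export
patternSummary <- function(segset) {
  if (isTRUE(segset@self))
    stop("patternSummary expects a cross-genome comparison")
  ma <- mergeSegments(segset, side = "a")
  mb <- mergeSegments(segset, side = "b")
  segRegA <- stats::setNames(ma$members$region_id, ma$members$segment_id)
  segRegB <- stats::setNames(mb$members$region_id, mb$members$segment_id)
  segs <- segmentTable(segset)$segment_id
  link <- data.frame(region_a = unname(segRegA[segs]),
                     region_b = unname(segRegB[segs]),
                     stringsAsFactors = FALSE)
  link <- link[!duplicated(link), , drop = FALSE]
  perB <- as.data.frame(table(link$region_b), stringsAsFactors = FALSE)
  names(perB) <- c("region_b", "n_a_regions")
  perA <- as.data.frame(table(link$region_a), stringsAsFactors = FALSE)
  names(perA) <- c("region_a", "n_b_regions")
  modal <- function(x) if (length(x)) as.integer(names(which.max(table(x)))) else NA_integer_
  modalA <- modal(perB$n_a_regions)
  modalB <- modal(perA$n_b_regions)
  list(perRegionB = perB, perRegionA = perA, modalA = modalA, modalB = modalB,
       pattern = sprintf("%d:%d", modalA, modalB))
}
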