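## Gene-tree based placement of anchor-pair duplication events on a species
## tree: family filtering, NJ gene trees with column-resampling bootstrap,
## outgroup/midpoint rooting, LCA reconciliation (duplication / speciation /
## dubious node labels) and per-branch event counts.

#' Filter and merge gene families for phylogenomic placement
#'
#' Anchors with Ks above \code{maxKs} (or saturated) are dropped; when the
#' two genes of a surviving anchor fall into different families the families
#' are merged (a clustering artefact); retained families must have at most
#' \code{maxSize} members, at least one surviving anchor pair and at least
#' one outgroup gene (needed for rooting).
#'
#' @param families named list of member gene-id vectors.
#' @param anchors data.frame \code{gene_a}, \code{gene_b} and optionally
#'   \code{ks}.
#' @param geneSpecies named character vector mapping gene id to species.
#' @param outgroupSpecies species label(s) of the outgroup.
#' @param maxKs anchor Ks ceiling (default 5); anchors with NA/non-finite Ks
#'   are dropped too.
#' @param maxSize largest retained family (default 300).
#' @return List with \code{families} (merged, filtered, named list),
#'   \code{anchors} (surviving anchors with a \code{family} column).
#' @export
filterFamiliesForPlacement <- function(families, anchors, geneSpecies,
                                       outgroupSpecies, maxKs = 5,
                                       maxSize = 300) {
  anchors <- as.data.frame(anchors, stringsAsFactors = FALSE)
  if (!is.null(anchors$ks))
    anchors <- anchors[is.finite(anchors$ks) & anchors$ks <= maxKs, , drop = FALSE]
  fam <- families
  gene2fam <- stats::setNames(rep(names(fam), lengths(fam)),
                              unlist(fam, use.names = FALSE))
  fa <- gene2fam[anchors$gene_a]; fb <- gene2fam[anchors$gene_b]
  keepAnchor <- !is.na(fa) & !is.na(fb)
  anchors <- anchors[keepAnchor, , drop = FALSE]
  fa <- fa[keepAnchor]; fb <- fb[keepAnchor]
  ## merge families bridged by an anchor (union-find over family ids)
  parent <- stats::setNames(names(fam), names(fam))
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(fa)) {
    ra <- find(fa[[k]]); rb <- find(fb[[k]])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  root <- vapply(names(fam), find, character(1))
  merged <- lapply(split(fam, root), function(fs) sort(unique(unlist(fs))))
  gene2fam <- stats::setNames(rep(names(merged), lengths(merged)),
                              unlist(merged, use.names = FALSE))
  anchors$family <- unname(gene2fam[anchors$gene_a])
  keepFam <- vapply(names(merged), function(f) {
    mem <- merged[[f]]
    length(mem) <= maxSize &&
      any(anchors$family == f) &&
      any(geneSpecies[mem] %in% outgroupSpecies)
  }, logical(1))
  merged <- merged[keepFam]
  anchors <- anchors[anchors$family %in% names(merged), , drop = FALSE]
  rownames(anchors) <- NULL
  list(families = merged, anchors = anchors)
}

## Poisson-corrected amino-acid distance matrix from aligned codon sequences.
## p = 1 saturation is capped at the largest finite distance + 1.
.poissonAaDist <- function(aaMat) {
  n <- nrow(aaMat)
  d <- matrix(0, n, n, dimnames = list(rownames(aaMat), rownames(aaMat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cmp <- !is.na(aaMat[i, ]) & !is.na(aaMat[j, ])
    p <- if (any(cmp)) mean(aaMat[i, cmp] != aaMat[j, cmp]) else 1
    d[i, j] <- d[j, i] <- if (p >= 1) Inf else -log(1 - p)
  }
  if (any(!is.finite(d))) {
    cap <- max(c(0, d[is.finite(d)])) + 1
    d[!is.finite(d)] <- cap
  }
  d
}

## canonical key of the bipartition induced by the tips below a node: the
## side not containing the alphabetically first tip, sorted
.splitKey <- function(tipsBelow, allTips) {
  ref <- sort(allTips)[1L]
  if (ref %in% tipsBelow) tipsBelow <- setdiff(allTips, tipsBelow)
  paste(sort(tipsBelow), collapse = "\r")
}

## tip labels below every node (postorder accumulation)
.tipSets <- function(phy) {
  ntip <- ape::Ntip(phy)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    sets[[eo[k, 1L]]] <- c(sets[[eo[k, 1L]]], sets[[eo[k, 2L]]])
  sets
}

## non-trivial bipartition keys present in one tree
.treeSplitKeys <- function(phy) {
  ntip <- ape::Ntip(phy)
  sets <- .tipSets(phy)
  all <- phy$tip.label
  keys <- character(0)
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    side <- sets[[v]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    keys <- c(keys, .splitKey(side, all))
  }
  unique(keys)
}

## write per-node support labels (percent) from bipartition counts;
## trivial splits get 100, unseen splits 0, the root an empty label
.attachSupports <- function(phy, counts, B) {
  ntip <- ape::Ntip(phy)
  sets <- .tipSets(phy)
  all <- phy$tip.label
  root <- ntip + 1L
  lab <- character(phy$Nnode)
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    side <- sets[[v]]
    if (v == root && length(side) == ntip) { lab[v - ntip] <- ""; next }
    if (length(side) <= 1L || length(side) >= ntip - 1L) {
      lab[v - ntip] <- "100"; next
    }
    cnt <- counts[.splitKey(side, all)]
    if (is.na(cnt)) cnt <- 0
    lab[v - ntip] <- as.character(round(100 * cnt / B, 1))
  }
  phy$node.label <- lab
  phy
}

#' Neighbor-joining gene tree with column-resampling bootstrap support
#'
#' Builds an unrooted NJ tree on Poisson-corrected amino-acid distances
#' (-ln(1 - p) on the translated codon alignment) and attaches per-branch
#' bootstrap support: codon columns are resampled with replacement B times,
#' distances and NJ recomputed, and support is the percentage of replicates
#' containing each internal bipartition. Deterministic given the RNG seed.
#'
#' @param cds named coding sequences of the family members (aligned; equal
#'   lengths).
#' @param B bootstrap replicates (default 200).
#' @return An unrooted \code{phylo} with \code{node.label} holding support
#'   percentages (root label empty).
#' @export
buildGeneTree <- function(cds, B = 200) {
  cds <- .asCdsVector(cds)
  if (length(cds) < 3L) stop("gene tree needs at least 3 sequences")
  idx <- lapply(names(cds), function(g) .codonIndices(cds[[g]], g))
  L <- unique(lengths(idx))
  if (length(L) != 1L) stop("sequences must be aligned (equal codon counts)")
  aaMat <- do.call(rbind, lapply(idx, .translateCodons))
  rownames(aaMat) <- names(cds)
  tree <- ape::nj(stats::as.dist(.poissonAaDist(aaMat)))
  keys <- character(0)
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    bt <- ape::nj(stats::as.dist(.poissonAaDist(aaMat[, cols, drop = FALSE])))
    keys <- c(keys, .treeSplitKeys(bt))
  }
  counts <- table(keys)
  tree <- .attachSupports(tree, counts, B)
  attr(tree, "splitCounts") <- counts
  attr(tree, "splitB") <- B
  tree
}

#' Root a gene tree on the outgroup, falling back to midpoint rooting
#'
#' Roots on the edge subtending the outgroup genes if they form a clade on
#' some rooting of the unrooted tree; otherwise midpoint rooting is applied.
#' Node labels are treated as edge (support) labels so bootstrap values stay
#' attached to the correct branches through re-rooting.
#'
#' @param tree unrooted \code{phylo} (e.g. from \code{\link{buildGeneTree}}).
#' @param outgroupTips tip labels of the outgroup genes present in the tree;
#'   empty means midpoint rooting directly.
#' @return A rooted \code{phylo}; attribute \code{"rooting"} records
#'   \code{"outgroup"} or \code{"midpoint"}.
#' @export
rootGeneTree <- function(tree, outgroupTips = character(0)) {
  outgroupTips <- intersect(outgroupTips, tree$tip.label)
  rooted <- NULL
  how <- "midpoint"
  if (length(outgroupTips)) {
    rooted <- tryCatch(
      ape::root(tree, outgroup = outgroupTips, resolve.root = TRUE,
                edgelabel = TRUE),
      error = function(e) NULL)
    if (!is.null(rooted)) how <- "outgroup"
  }
  if (is.null(rooted))
    rooted <- phangorn::midpoint(tree, node.labels = "support")
  ## supports are bipartition properties: recompute the labels on the rooted
  ## topology from the stored bootstrap split counts when available
  counts <- attr(tree, "splitCounts")
  if (!is.null(counts))
    rooted <- .attachSupports(rooted, counts, attr(tree, "splitB"))
  attr(rooted, "rooting") <- how
  rooted
}

## parent pointer vector for a phylo: parent[node] (0 for root)
.parentVec <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

## list of descendant-or-self species-tree node sets, for strict-ancestor tests
.ancestorChain <- function(parent, node) {
  out <- integer(0)
  while (node != 0L) { out <- c(out, node); node <- parent[node] }
  out
}

#' Classify gene-tree nodes by LCA reconciliation with the species tree
#'
#' Each internal node is mapped to the MRCA (in the species tree) of the
#' species below it. A node is a duplication node when at least two of its
#' child clades share a species (it has at least one pair of paralogues); a
#' non-duplication node is a speciation node when its map is a strict
#' ancestor of every child's map (congruent with the species phylogeny),
#' and dubious otherwise.
#'
#' @param geneTree rooted \code{phylo} whose \code{node.label} carries
#'   bootstrap support (may be missing).
#' @param speciesTree rooted species \code{phylo}.
#' @param geneSpecies named character vector mapping gene id to species.
#' @return data.frame, one row per gene-tree internal node: \code{node},
#'   \code{label}, \code{species_node} (species-tree node number),
#'   \code{species_node_id} (stable id), \code{support}.
#' @export
classifyNodes <- function(geneTree, speciesTree, geneSpecies) {
  ntip <- ape::Ntip(geneTree)
  nnode <- geneTree$Nnode
  tipSpecies <- unname(geneSpecies[geneTree$tip.label])
  bad <- is.na(tipSpecies) | !(tipSpecies %in% speciesTree$tip.label)
  if (any(bad))
    stop(sprintf("species of gene '%s' missing from the species tree",
                 geneTree$tip.label[bad][1L]))
  ## species sets below every gene-tree node (postorder accumulation)
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tipSpecies[i]
  eo <- ape::reorder.phylo(geneTree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    sets[[eo[k, 1L]]] <- unique(c(sets[[eo[k, 1L]]], sets[[eo[k, 2L]]]))
  }
  ## species-tree MRCA per species set (memoised)
  spTips <- stats::setNames(seq_along(speciesTree$tip.label),
                            speciesTree$tip.label)
  mrcaCache <- new.env(parent = emptyenv())
  spMrca <- function(spp) {
    key <- paste(sort(spp), collapse = "|")
    if (!is.null(mrcaCache[[key]])) return(mrcaCache[[key]])
    v <- if (length(spp) == 1L) unname(spTips[spp])
         else ape::getMRCA(speciesTree, spp)
    mrcaCache[[key]] <- v
    v
  }
  spParent <- .parentVec(speciesTree)
  support <- rep(NA_real_, nnode)
  if (!is.null(geneTree$node.label))
    support <- suppressWarnings(as.numeric(geneTree$node.label))
  children <- split(geneTree$edge[, 2L], geneTree$edge[, 1L])
  internal <- ntip + seq_len(nnode)
  label <- character(nnode); spNode <- integer(nnode)
  for (v in internal) {
    kids <- children[[as.character(v)]]
    kidSets <- lapply(kids, function(k) sets[[k]])
    dup <- FALSE
    if (length(kidSets) >= 2L) {
      for (i in seq_len(length(kidSets) - 1L)) {
        for (j in (i + 1L):length(kidSets)) {
          if (length(intersect(kidSets[[i]], kidSets[[j]]))) { dup <- TRUE; break }
        }
        if (dup) break
      }
    }
    map <- spMrca(sets[[v]])
    spNode[v - ntip] <- map
    if (dup) { label[v - ntip] <- "duplication"; next }
    kidMaps <- vapply(kidSets, spMrca, integer(1))
    strictAnc <- vapply(kidMaps, function(km) {
      km != map && map %in% .ancestorChain(spParent, km)[-1L]
    }, logical(1))
    label[v - ntip] <- if (all(strictAnc)) "speciation" else "dubious"
  }
  data.frame(node = internal, label = label, species_node = spNode,
             species_node_id = speciesNodeId(speciesTree, spNode),
             support = support, stringsAsFactors = FALSE)
}

#' Place one anchor pair's duplication on the species tree
#'
#' The coalescent node of the two anchor genes must be a duplication node
#' (otherwise the anchor is reported unplaced). Its species map is the lower
#' bound of the duplication event; tracing rootwards (continuing past dubious
#' nodes) to the first speciation node gives the upper bound, or a root-open
#' interval when none exists. When lower and upper bound are connected by a
#' single species-tree branch the event is assigned to that branch. Support
#' is the bootstrap value on the branch leading to the coalescent node.
#'
#' @param geneA,geneB tip labels of the anchor pair.
#' @param geneTree rooted \code{phylo}.
#' @param classification output of \code{\link{classifyNodes}} for this tree.
#' @param speciesTree rooted species \code{phylo}.
#' @return One-row data.frame: \code{gene_a}, \code{gene_b}, \code{placed},
#'   \code{reason}, \code{lower_id}, \code{upper_id} (NA = root-open),
#'   \code{n_branches}, \code{assigned_branch} (child node id of the branch,
#'   or NA), \code{support}, \code{n_dubious_crossed}.
#' @export
placeAnchor <- function(geneA, geneB, geneTree, classification, speciesTree) {
  unplaced <- function(reason) data.frame(
    gene_a = geneA, gene_b = geneB, placed = FALSE, reason = reason,
    lower_id = NA_character_, upper_id = NA_character_,
    n_branches = NA_integer_, assigned_branch = NA_character_,
    support = NA_real_, n_dubious_crossed = NA_integer_,
    stringsAsFactors = FALSE)
  tips <- match(c(geneA, geneB), geneTree$tip.label)
  if (anyNA(tips)) return(unplaced("anchor genes not in the same tree"))
  mrca <- ape::getMRCA(geneTree, c(geneA, geneB))
  cl <- classification[match(mrca, classification$node), ]
  if (cl$label != "duplication")
    return(unplaced(sprintf("coalescent node is a %s node", cl$label)))
  parent <- .parentVec(geneTree)
  node <- parent[mrca]; nDub <- 0L; upper <- NA_integer_
  while (node != 0L) {
    lab <- classification$label[match(node, classification$node)]
    if (lab == "speciation") { upper <- node; break }
    if (lab == "dubious") nDub <- nDub + 1L
    node <- parent[node]
  }
  lowerSp <- cl$species_node
  lowerId <- cl$species_node_id
  if (is.na(upper)) {
    return(data.frame(gene_a = geneA, gene_b = geneB, placed = TRUE,
                      reason = "root-open interval (no speciation ancestor)",
                      lower_id = lowerId, upper_id = NA_character_,
                      n_branches = NA_integer_,
                      assigned_branch = NA_character_,
                      support = cl$support, n_dubious_crossed = nDub,
                      stringsAsFactors = FALSE))
  }
  upperSp <- classification$species_node[match(upper, classification$node)]
  upperId <- classification$species_node_id[match(upper, classification$node)]
  spParent <- .parentVec(speciesTree)
  chain <- .ancestorChain(spParent, lowerSp)
  pos <- match(upperSp, chain)
  if (is.na(pos)) return(unplaced("species maps not nested"))
  nBranches <- pos - 1L
  assigned <- if (nBranches == 1L) lowerId else NA_character_
  data.frame(gene_a = geneA, gene_b = geneB, placed = TRUE,
             reason = if (nBranches == 1L) "single-branch interval"
                      else sprintf("interval spans %d branches", nBranches),
             lower_id = lowerId, upper_id = upperId,
             n_branches = nBranches, assigned_branch = assigned,
             support = cl$support, n_dubious_crossed = nDub,
             stringsAsFactors = FALSE)
}

#' Place all anchors of a set of families
#'
#' Per family: build the NJ gene tree with bootstrap support, root on the
#' outgroup (midpoint fallback), classify nodes by LCA reconciliation and
#' place every anchor pair of the family.
#'
#' @param filtered output of \code{\link{filterFamiliesForPlacement}}.
#' @param cds named coding sequences.
#' @param speciesTree rooted species \code{phylo}.
#' @param geneSpecies named character vector gene id -> species.
#' @param outgroupSpecies outgroup species label(s).
#' @param B bootstrap replicates per gene tree.
#' @return data.frame of placements (one row per anchor) with a
#'   \code{family} column.
#' @export
placeAnchors <- function(filtered, cds, speciesTree, geneSpecies,
                         outgroupSpecies, B = 200) {
  out <- list()
  for (f in names(filtered$families)) {
    members <- filtered$families[[f]]
    fAnch <- filtered$anchors[filtered$anchors$family == f, , drop = FALSE]
    if (!nrow(fAnch)) next
    if (length(members) < 3L) {
      for (k in seq_len(nrow(fAnch)))
        out[[length(out) + 1L]] <- cbind(
          data.frame(family = f, stringsAsFactors = FALSE),
          data.frame(gene_a = fAnch$gene_a[k], gene_b = fAnch$gene_b[k],
                     placed = FALSE, reason = "family too small for a tree",
                     lower_id = NA_character_, upper_id = NA_character_,
                     n_branches = NA_integer_,
                     assigned_branch = NA_character_, support = NA_real_,
                     n_dubious_crossed = NA_integer_,
                     stringsAsFactors = FALSE))
      next
    }
    tree <- buildGeneTree(cds[members], B = B)
    og <- members[geneSpecies[members] %in% outgroupSpecies]
    rooted <- rootGeneTree(tree, og)
    cls <- classifyNodes(rooted, speciesTree, geneSpecies)
    for (k in seq_len(nrow(fAnch))) {
      p <- placeAnchor(fAnch$gene_a[k], fAnch$gene_b[k], rooted, cls,
                       speciesTree)
      out[[length(out) + 1L]] <- cbind(data.frame(family = f,
                                                  stringsAsFactors = FALSE), p)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(family = character(0), gene_a = character(0),
                      gene_b = character(0), placed = logical(0),
                      reason = character(0), lower_id = character(0),
                      upper_id = character(0), n_branches = integer(0),
                      assigned_branch = character(0), support = numeric(0),
                      n_dubious_crossed = integer(0))
  rownames(res) <- NULL
  res
}

#' Count duplication events per species-tree branch
#'
#' For every branch (identified by the stable id of its child node) and every
#' support threshold: the number of distinct anchor pairs and distinct gene
#' families with at least one qualifying single-branch placement. Counts at a
#' higher threshold can never exceed counts at a lower one.
#'
#' @param placements data.frame from \code{\link{placeAnchors}}.
#' @param supportThresholds bootstrap percentage thresholds (default 50, 80).
#' @param geneSpecies optional named vector gene id -> species; when given, a
#'   per-species anchor-pair breakdown is attached as attribute
#'   \code{"bySpecies"}.
#' @return data.frame \code{branch}, \code{threshold},
#'   \code{n_anchor_pairs}, \code{n_families}.
#' @export
countEventsPerBranch <- function(placements, supportThresholds = c(50, 80),
                                 geneSpecies = NULL) {
  q <- placements[placements$placed & !is.na(placements$assigned_branch), ,
                  drop = FALSE]
  rows <- list(); sprows <- list()
  for (thr in sort(supportThresholds)) {
    qq <- q[!is.na(q$support) & q$support >= thr, , drop = FALSE]
    for (br in sort(unique(q$assigned_branch))) {
      qb <- qq[qq$assigned_branch == br, , drop = FALSE]
      pairKey <- paste(pmin(qb$gene_a, qb$gene_b), pmax(qb$gene_a, qb$gene_b))
      rows[[length(rows) + 1L]] <- data.frame(
        branch = br, threshold = thr,
        n_anchor_pairs = length(unique(pairKey)),
        n_families = length(unique(qb$family)), stringsAsFactors = FALSE)
      if (!is.null(geneSpecies) && nrow(qb)) {
        sp <- unname(geneSpecies[qb$gene_a])
        tab <- table(sp[!duplicated(pairKey)])
        sprows[[length(sprows) + 1L]] <- data.frame(
          branch = br, threshold = thr, species = names(tab),
          n_anchor_pairs = as.integer(tab), stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(branch = character(0), threshold = numeric(0),
               n_anchor_pairs = integer(0), n_families = integer(0))
  rownames(res) <- NULL
  if (!is.null(geneSpecies))
    attr(res, "bySpecies") <- if (length(sprows)) do.call(rbind, sprows) else NULL
  res
}
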