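## Paranome construction and the redundancy-corrected (node-weighted) Ks age
## distribution. A family of n members yields n(n-1)/2 pairwise Ks estimates
## but only n-1 duplication events; weighting every pair at a duplication node
## by 1/m (m = number of cross-clade pairs at that node) restores one unit of
## mass per event.

#' Build gene families as connected components of the similarity graph
#'
#' Families are the connected components of the homology graph after applying
#' the E-value cutoff; singleton genes are discarded. Connected components
#' stand in for Markov clustering here: the downstream redundancy correction
#' is independent of the clustering backend, and components at a stringent
#' cutoff give a deterministic, oracle-checkable partition.
#'
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b} and
#'   optionally \code{evalue}.
#' @param evalueCutoff drop edges with \code{evalue > evalueCutoff} before
#'   taking components (ignored when there is no evalue column).
#' @return Named list of character vectors (member gene ids, sorted), names
#'   \code{fam000001}, ... in order of each family's smallest member id.
#' @export
buildFamilies <- function(edges, evalueCutoff = 1e-10) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.null(edges$evalue))
    edges <- edges[edges$evalue <= evalueCutoff, , drop = FALSE]
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  if (!nrow(edges)) return(stats::setNames(list(), character(0)))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE)
  comp <- igraph::components(g)
  fams <- split(names(comp$membership), comp$membership)
  fams <- lapply(fams, sort)
  fams <- fams[lengths(fams) >= 2L]
  fams <- fams[order(vapply(fams, `[`, character(1), 1L))]
  names(fams) <- sprintf("fam%06d", seq_along(fams))
  fams
}

#' Split a family into subfamilies with bounded pairwise Ks
#'
#' Complete-linkage clustering on the pairwise Ks matrix, cut so that within
#' every subfamily all pairwise Ks values are at most \code{maxKs} (the
#' stricter, all-pairs reading of "did not exceed"); saturated or undefined
#' pairs are treated as exceeding the bound. A single-linkage variant is
#' available via \code{linkage = "single"}.
#'
#' @param members character vector of member gene ids.
#' @param ksMatrix symmetric numeric matrix of pairwise Ks values indexed by
#'   gene id (NA/Inf for saturated or undefined pairs).
#' @param maxKs subfamily Ks ceiling (default 5).
#' @param linkage \code{"complete"} (default) or \code{"single"}.
#' @return List of character vectors, one per subfamily (singletons included).
#' @export
splitSubfamilies <- function(members, ksMatrix, maxKs = 5,
                             linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  members <- sort(as.character(members))
  if (length(members) <= 1L) return(list(members))
  m <- ksMatrix[members, members, drop = FALSE]
  big <- 2 * maxKs + max(c(1, m[is.finite(m)]), na.rm = TRUE)
  m[!is.finite(m)] <- big
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  grp <- stats::cutree(hc, h = maxKs)
  unname(lapply(split(members, grp), sort))
}

#' Average-linkage (UPGMA) subfamily tree on Ks distances
#'
#' The subfamily tree only serves to group gene pairs by duplication node for
#' the 1/m weighting; UPGMA on an approximately ultrametric paranome is
#' adequate and fully deterministic (members are sorted lexicographically
#' before clustering so ties break identically across runs). A
#' neighbour-joining alternative is available for strongly non-clock-like
#' subfamilies.
#'
#' @param ksMatrix symmetric matrix of finite pairwise Ks values indexed by
#'   the subfamily's gene ids.
#' @param method \code{"upgma"} (default) or \code{"nj"}.
#' @return An \code{hclust} object (heights = linkage Ks at each merge).
#' @export
subfamilyTree <- function(ksMatrix, method = c("upgma", "nj")) {
  method <- match.arg(method)
  ids <- sort(rownames(ksMatrix))
  if (length(ids) < 2L) stop("subfamily tree needs >= 2 members")
  m <- ksMatrix[ids, ids, drop = FALSE]
  if (any(!is.finite(m[upper.tri(m)])))
    stop("subfamily tree requires finite pairwise Ks values")
  if (method == "upgma") {
    stats::hclust(stats::as.dist(m), method = "average")
  } else {
    phy <- ape::nj(stats::as.dist(m))
    ## convert to a rooted ultrametricised hclust via UPGMA on cophenetic
    ## distances of the NJ tree (keeps the downstream interface uniform)
    stats::hclust(stats::as.dist(ape::cophenetic.phylo(phy)[ids, ids]),
                  method = "average")
  }
}

#' Node-weighted Ks entries of a subfamily tree
#'
#' Every internal node of the subfamily tree is treated as a duplication node.
#' For a node with child clades L and R, all m = |L| * |R| cross-clade pairs
#' enter the distribution with weight 1/m, so the weights of one duplication
#' event sum to one and a subfamily of n members carries total mass n - 1.
#'
#' @param tree an \code{hclust} from \code{\link{subfamilyTree}}.
#' @param ksMatrix symmetric pairwise Ks matrix indexed by gene id.
#' @param subfamilyId label recorded in the output.
#' @return data.frame with \code{gene_a}, \code{gene_b}, \code{ks},
#'   \code{weight}, \code{m}, \code{node_id}, \code{subfamily_id}.
#' @export
weightNodeKs <- function(tree, ksMatrix, subfamilyId = "sf1") {
  labs <- tree$labels
  nleaf <- length(labs)
  merges <- tree$merge
  clade <- vector("list", nrow(merges))
  out <- vector("list", nrow(merges))
  for (k in seq_len(nrow(merges))) {
    left <- if (merges[k, 1L] < 0) labs[-merges[k, 1L]] else clade[[merges[k, 1L]]]
    right <- if (merges[k, 2L] < 0) labs[-merges[k, 2L]] else clade[[merges[k, 2L]]]
    clade[[k]] <- c(left, right)
    pairs <- expand.grid(l = left, r = right, stringsAsFactors = FALSE)
    m <- nrow(pairs)
    ga <- pmin(pairs$l, pairs$r); gb <- pmax(pairs$l, pairs$r)
    out[[k]] <- data.frame(
      gene_a = ga, gene_b = gb,
      ks = ksMatrix[cbind(pairs$l, pairs$r)],
      weight = rep(1 / m, m), m = m,
      node_id = sprintf("%s:n%d", subfamilyId, k),
      subfamily_id = subfamilyId, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  stopifnot(nrow(res) == nleaf * (nleaf - 1) / 2)
  res
}

#' Redundancy-corrected Ks age distribution of a paranome
#'
#' End-to-end driver: build families from the homology graph, estimate
#' pairwise Ks within each family (NG86 + Jukes-Cantor), split families into
#' subfamilies with pairwise Ks at most \code{subfamilyMaxKs}, build a UPGMA
#' tree per subfamily and emit one weighted entry per gene pair per
#' duplication node.
#'
#' @param cds named coding sequences.
#' @param edges homology edges (within one species for a paranome).
#' @param config a \linkS4class{PipelineConfig}.
#' @return A \linkS4class{KsDistribution} with source \code{"paranome"}.
#' @export
paranomeKs <- function(cds, edges, config = pipelineConfig()) {
  fams <- buildFamilies(edges, config@paranomeEvalueCutoff)
  entries <- vector("list", 0L)
  for (fid in names(fams)) {
    members <- fams[[fid]]
    ksm <- .ksMatrix(cds, members)
    subs <- splitSubfamilies(members, ksm, config@subfamilyMaxKs)
    si <- 0L
    for (sub in subs) {
      if (length(sub) < 2L) next
      si <- si + 1L
      tr <- subfamilyTree(ksm[sub, sub, drop = FALSE])
      entries[[length(entries) + 1L]] <-
        weightNodeKs(tr, ksm, sprintf("%s.%d", fid, si))
    }
  }
  ent <- if (length(entries)) do.call(rbind, entries) else
    data.frame(gene_a = character(0), gene_b = character(0),
               ks = numeric(0), weight = numeric(0), m = integer(0),
               node_id = character(0), subfamily_id = character(0))
  KsDistribution(ent, source = "paranome")
}

## pairwise Ks matrix for a set of genes; saturated/undefined -> Inf
.ksMatrix <- function(cds, members) {
  n <- length(members)
  m <- matrix(0, n, n, dimnames = list(members, members))
  if (n < 2L) return(m)
  pr <- t(utils::combn(members, 2L))
  kk <- ksPairwise(cds, data.frame(a = pr[, 1L], b = pr[, 2L]))
  v <- ifelse(kk$saturated | !is.finite(kk$ks), Inf, kk$ks)
  m[cbind(kk$gene_a, kk$gene_b)] <- v
  m[cbind(kk$gene_b, kk$gene_a)] <- v
  m
}
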