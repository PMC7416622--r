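## Genome-evolution simulator: gene families descending along a known species
## tree, WGD events with partial retention, fractionation, inversions and
## codon sequences whose pairwise synonymous divergence tracks event ages.
## Every dataset carries full ground truth (families, genealogy, true anchor
## pairs, true pairwise Ks) so downstream inference can be validated.

#' SimConfig: parameters of a simulated genome-evolution scenario
#'
#' Branch lengths of the species tree are per-lineage expected Ks; WGD ages
#' and divergence times are quoted in pairwise Ks (an event of age 1.0 sits
#' at per-lineage depth 0.5 above the tips of its branch, so the surviving
#' duplicate pairs show pairwise Ks near 1.0).
#'
#' @slot speciesTree rooted \code{phylo}, branch lengths in per-lineage Ks.
#' @slot wgdEvents data.frame with \code{branch} (stable id of the branch's
#'   child node, see \code{\link{speciesNodeId}}), \code{age_ks} (pairwise
#'   Ks age) and \code{retention} (per-gene duplicate retention probability).
#' @slot nFamilies,genesPerScaffold,nScaffolds genome layout; families fill
#'   scaffolds row-major.
#' @slot fractionationProb per-gene, per-Ks-unit loss rate of WGD duplicates.
#' @slot nInversions inversions applied to each tip genome.
#' @slot cdsCodons codons per coding sequence (>= 50).
#' @slot omega acceptance probability of nonsynonymous proposals (dN/dS
#'   target).
#' @slot smallScaleDupRate per-gene, per-Ks-unit tandem duplication rate.
#' @slot seed RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(speciesTree = "ANY", wgdEvents = "data.frame",
                 nFamilies = "numeric", genesPerScaffold = "numeric",
                 nScaffolds = "numeric", fractionationProb = "numeric",
                 nInversions = "numeric", cdsCodons = "numeric",
                 omega = "numeric", smallScaleDupRate = "numeric",
                 seed = "numeric"))

setValidity("SimConfig", function(object) {
  phy <- object@speciesTree
  if (!inherits(phy, "phylo")) return("speciesTree must be a phylo object")
  if (is.null(phy$edge.length)) return("speciesTree needs branch lengths (Ks units)")
  ev <- object@wgdEvents
  if (nrow(ev)) {
    if (!all(c("branch", "age_ks", "retention") %in% names(ev)))
      return("wgdEvents needs columns branch, age_ks, retention")
    if (any(ev$retention < 0 | ev$retention > 1))
      return("retention must lie in [0,1]")
    if (any(ev$age_ks <= 0)) return("age_ks must be positive")
    ids <- speciesNodeId(phy)
    if (!all(ev$branch %in% ids))
      return(sprintf("unknown branch id '%s'", setdiff(ev$branch, ids)[1L]))
    pos <- .eventPositions(phy, ev)
    if (any(pos$distFromParent < -1e-9 | pos$distFromParent > pos$edgeLen + 1e-9))
      return("a WGD age is infeasible on its branch (older than the branch or younger than the clade below)")
  }
  if (object@cdsCodons < 50) return("cdsCodons must be >= 50")
  if (object@nFamilies < 1) return("nFamilies must be >= 1")
  if (object@nScaffolds * object@genesPerScaffold < object@nFamilies)
    return("scaffold layout too small for nFamilies")
  if (object@fractionationProb < 0 || object@smallScaleDupRate < 0 ||
      object@nInversions < 0)
    return("rates must be >= 0")
  TRUE
})

#' Construct a SimConfig
#'
#' @param speciesTree rooted \code{phylo} with branch lengths in per-lineage
#'   Ks units (or a Newick string).
#' @param wgdEvents data.frame \code{branch}, \code{age_ks},
#'   \code{retention}; default none.
#' @param nFamilies number of gene families (default 100).
#' @param genesPerScaffold genes per scaffold (default 25).
#' @param nScaffolds number of scaffolds (default: smallest number that
#'   holds \code{nFamilies}).
#' @param fractionationProb per-gene per-Ks-unit loss rate of WGD duplicates
#'   (default 0).
#' @param nInversions inversions per tip genome (default 0).
#' @param cdsCodons codons per sequence (default 300).
#' @param omega nonsynonymous acceptance probability (default 0.2).
#' @param smallScaleDupRate per-gene per-Ks-unit tandem duplication rate
#'   (default 0).
#' @param seed RNG seed (default 1).
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(speciesTree, wgdEvents = NULL, nFamilies = 100,
                      genesPerScaffold = 25, nScaffolds = NULL,
                      fractionationProb = 0, nInversions = 0,
                      cdsCodons = 300, omega = 0.2, smallScaleDupRate = 0,
                      seed = 1) {
  if (is.character(speciesTree)) speciesTree <- ape::read.tree(text = speciesTree)
  if (is.null(wgdEvents))
    wgdEvents <- data.frame(branch = character(0), age_ks = numeric(0),
                            retention = numeric(0))
  if (is.null(nScaffolds)) nScaffolds <- ceiling(nFamilies / genesPerScaffold)
  new("SimConfig", speciesTree = speciesTree,
      wgdEvents = as.data.frame(wgdEvents, stringsAsFactors = FALSE),
      nFamilies = nFamilies, genesPerScaffold = genesPerScaffold,
      nScaffolds = nScaffolds, fractionationProb = fractionationProb,
      nInversions = nInversions, cdsCodons = cdsCodons, omega = omega,
      smallScaleDupRate = smallScaleDupRate, seed = seed)
}

#' GroundTruth: known truth of a simulated dataset
#'
#' @slot genes data.frame \code{gene_id}, \code{species}, \code{family},
#'   \code{scaffold}, \code{rank}, \code{strand}.
#' @slot events data.frame \code{event_id}, \code{branch}, \code{age_ks},
#'   \code{retention}.
#' @slot anchors data.frame of true surviving duplicate pairs:
#'   \code{gene_a}, \code{gene_b}, \code{species}, \code{event_id},
#'   \code{true_ks}.
#' @slot pairKs data.frame of true divergence for every within-family gene
#'   pair: \code{gene_a}, \code{gene_b}, \code{true_ks}.
#' @slot nCapped number of sequence evolutions that hit the saturation cap.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(genes = "data.frame", events = "data.frame",
                 anchors = "data.frame", pairKs = "data.frame",
                 nCapped = "numeric"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d genes, %d WGD event(s), %d true anchor pairs\n",
              nrow(object@genes), nrow(object@events), nrow(object@anchors)))
})

#' @describeIn GroundTruth true anchor pair accessor
#' @param object a \code{GroundTruth}.
#' @export
trueAnchors <- function(object) object@anchors

#' @describeIn GroundTruth gene table accessor
#' @export
truthGenes <- function(object) object@genes

## --- sequence-level machinery -------------------------------------------

.randomCodons <- function(n) {
  tabs <- .ng86Tables()
  ok <- which(!tabs$isStop)
  sample(ok, n, replace = TRUE)
}

.idxToString <- function(idx) paste(.ng86env$codons[idx], collapse = "")

## Raw NG86 synonymous-difference target corresponding to a Jukes-Cantor
## corrected synonymous distance of ks: the expected proportion of observed
## synonymous differences after ks substitutions per synonymous site is
## (3/4)(1 - exp(-4 ks / 3)); targeting the raw count at that expectation
## makes the corrected estimate track ks (and JC distances compose
## additively across branch segments).
.rawSdMean <- function(ks, Ssites) Ssites * 0.75 * (1 - exp(-4 * ks / 3))

.evolveIdx <- function(idx, targetKs, omega) {
  tabs <- .ng86Tables()
  S <- sum(tabs$siteS[idx])
  target <- stats::rpois(1L, .rawSdMean(targetKs, S))
  maxIter <- as.integer(min(2e7, 5000 + 60 * length(idx) * (1 + 10 * targetKs)))
  aaCode <- match(tabs$aa, unique(tabs$aa))
  r <- .evolveCodonsCpp(idx, omega, target, tabs$SdTab, tabs$isStop,
                        aaCode, maxIter)
  r$targetSd <- target
  r
}

#' Evolve a coding sequence to a target synonymous divergence
#'
#' Proposal process: a uniform random site receives a uniform random
#' different base; proposals creating internal stops are rejected,
#' synonymous proposals are always accepted and nonsynonymous ones with
#' probability \code{omega}; mutation continues until the NG86 synonymous
#' difference count against the parent reaches a Poisson-drawn target whose
#' mean is calibrated so the Jukes-Cantor corrected Ks estimate tracks
#' \code{targetKs}. Unreachable targets (short sequences, saturation) are
#' capped and flagged. Uses R's RNG; call \code{set.seed} for
#' reproducibility.
#'
#' @param parentCds parent coding sequence (no internal stops).
#' @param targetKs desired synonymous substitutions per synonymous site
#'   (>= 0).
#' @param omega acceptance probability for nonsynonymous proposals.
#' @return List: \code{child} (character sequence), \code{targetSd},
#'   \code{realizedSd}, \code{capped}.
#' @export
evolveSequence <- function(parentCds, targetKs, omega = 0.2) {
  stopifnot(targetKs >= 0)
  idx <- .codonIndices(parentCds, "parentCds")
  if (anyNA(idx)) stop("parentCds contains ambiguous bases")
  r <- .evolveIdx(idx, targetKs, omega)
  list(child = .idxToString(r$codons), targetSd = r$targetSd,
       realizedSd = r$sd, capped = r$capped)
}

## --- genome-level operations on SpeciesGenome ---------------------------

#' Whole-genome duplication of a SpeciesGenome
#'
#' Appends a duplicated copy of every scaffold, then removes each duplicated
#' gene independently with probability \code{1 - retentionProb}; empty
#' duplicate scaffolds are dropped. Copies get a fresh \code{_w<k>} suffix.
#'
#' @param genome a \linkS4class{SpeciesGenome}.
#' @param retentionProb per-gene retention probability in [0,1].
#' @return Duplicated \linkS4class{SpeciesGenome}.
#' @export
applyWgd <- function(genome, retentionProb) {
  stopifnot(retentionProb >= 0, retentionProb <= 1)
  g <- geneTable(genome)
  if (!nrow(g)) return(genome)
  k <- 1L
  while (any(grepl(sprintf("_w%d$", k), g$gene_id))) k <- k + 1L
  dup <- g
  dup$gene_id <- paste0(dup$gene_id, sprintf("_w%d", k))
  dup$scaffold <- paste0(dup$scaffold, sprintf("_w%d", k))
  keep <- stats::runif(nrow(dup)) < retentionProb
  dup <- dup[keep, , drop = FALSE]
  if (nrow(dup)) {
    dup <- dup[order(dup$scaffold, dup$rank), , drop = FALSE]
    dup$rank <- unlist(lapply(split(seq_len(nrow(dup)), dup$scaffold),
                              seq_along), use.names = FALSE) - 1L
  }
  SpeciesGenome(speciesId(genome), rbind(g, dup))
}

#' Random inversions of contiguous rank windows
#'
#' Each inversion reverses a uniformly chosen contiguous rank interval of a
#' scaffold (scaffolds chosen with probability proportional to gene count)
#' and flips the strands inside the window.
#'
#' @param genome a \linkS4class{SpeciesGenome}.
#' @param n number of inversions.
#' @return Inverted \linkS4class{SpeciesGenome}.
#' @export
applyInversions <- function(genome, n) {
  g <- geneTable(genome)
  if (!nrow(g) || n < 1) return(genome)
  for (i in seq_len(n)) {
    sc <- sample(g$scaffold, 1L)
    rows <- which(g$scaffold == sc)
    k <- length(rows)
    ij <- sort(sample.int(k, 2L, replace = TRUE))
    win <- rows[order(g$rank[rows])][ij[1L]:ij[2L]]
    g$rank[win] <- rev(g$rank[win])
    g$strand[win] <- ifelse(g$strand[win] == "+", "-", "+")
  }
  SpeciesGenome(speciesId(genome), g)
}

## --- tree helpers --------------------------------------------------------

## distance from the root for every node
.rootDist <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  rd <- numeric(n)
  eo <- ape::reorder.phylo(phy, "postorder")
  ord <- rev(seq_len(nrow(eo$edge)))  # preorder
  for (k in ord) rd[eo$edge[k, 2L]] <- rd[eo$edge[k, 1L]] + eo$edge.length[k]
  rd
}

## max distance to a descendant tip for every node
.tipDepth <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  d <- numeric(n)
  eo <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]; c <- eo$edge[k, 2L]
    d[p] <- max(d[p], d[c] + eo$edge.length[k])
  }
  d
}

## resolve event positions: distFromParent along the child's stem edge
.eventPositions <- function(phy, ev) {
  ids <- speciesNodeId(phy)
  child <- match(ev$branch, ids)
  rd <- .rootDist(phy)
  td <- .tipDepth(phy)
  parent <- .parentVec(phy)
  edgeLen <- rd[child] - rd[parent[child]]
  ## event at per-lineage distance age/2 above the tips below the branch
  eventRootDist <- rd[child] + td[child] - ev$age_ks / 2
  data.frame(child = child, edgeLen = edgeLen,
             distFromParent = eventRootDist - rd[parent[child]],
             eventRootDist = eventRootDist)
}

## --- the simulator -------------------------------------------------------

#' Simulate a multi-species dataset with known WGD ground truth
#'
#' Families descend along the species tree; at each WGD event every scaffold
#' of the affected lineage is duplicated and each gene copy retained with
#' the event's retention probability; retained duplicates may subsequently be
#' lost at the fractionation rate; tip genomes receive random inversions.
#' Codon sequences evolve by the calibrated proposal process of
#' \code{\link{evolveSequence}}. The homology table contains one edge (in
#' both directions) for every within-family gene pair with bit-score proxy
#' (1 - protein p-distance) x protein length and E-value proxy
#' 10^(-bitscore/10) floored at 1e-180. Identical seeds give identical
#' datasets.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return List: \code{genomes} (named list of
#'   \linkS4class{SpeciesGenome}), \code{cds} (named character vector),
#'   \code{homology} (data.frame \code{gene_a}, \code{gene_b},
#'   \code{bitscore}, \code{evalue}), \code{speciesTree}, \code{truth}
#'   (\linkS4class{GroundTruth}), \code{config}.
#' @export
simulateDataset <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  tabs <- .ng86Tables()
  phy <- config@speciesTree
  ntip <- ape::Ntip(phy)
  rd <- .rootDist(phy)
  parent <- .parentVec(phy)
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  ev <- config@wgdEvents
  pos <- if (nrow(ev)) .eventPositions(phy, ev) else NULL
  if (nrow(ev)) ev$event_id <- sprintf("wgd%d", seq_len(nrow(ev)))

  genes <- new.env(parent = emptyenv())
  counter <- 0L
  capped <- 0L
  newGene <- function(seq, fam, tok, dep, strand) {
    counter <<- counter + 1L
    id <- sprintf("L%07d", counter)
    assign(id, list(seq = seq, fam = fam, tok = tok, dep = dep,
                    strand = strand), envir = genes)
    id
  }
  getG <- function(id) get(id, envir = genes)

  ## ancestral genome: families fill scaffolds row-major
  scafNames <- sprintf("s%02d", seq_len(config@nScaffolds))
  genome0 <- stats::setNames(vector("list", config@nScaffolds), scafNames)
  fam <- 1L
  for (s in scafNames) {
    ids <- character(0)
    while (length(ids) < config@genesPerScaffold && fam <= config@nFamilies) {
      ids <- c(ids, newGene(.randomCodons(config@cdsCodons), fam,
                            character(0), numeric(0), "+"))
      fam <- fam + 1L
    }
    genome0[[s]] <- ids
  }
  genome0 <- genome0[lengths(genome0) > 0L]

  evolveGenome <- function(genome, len, depthEnd) {
    if (len <= 0) return(genome)
    for (s in names(genome)) for (id in genome[[s]]) {
      g <- getG(id)
      r <- .evolveIdx(g$seq, len, config@omega)
      if (r$capped) capped <<- capped + 1L
      g$seq <- r$codons
      assign(id, g, envir = genes)
    }
    ## fractionation of WGD duplicates; tandem duplications
    pLoss <- 1 - exp(-config@fractionationProb * len)
    pDup <- 1 - exp(-config@smallScaleDupRate * len)
    if (pLoss > 0 || pDup > 0) {
      for (s in names(genome)) {
        ids <- genome[[s]]
        keep <- rep(TRUE, length(ids))
        extra <- vector("list", length(ids))
        for (i in seq_along(ids)) {
          g <- getG(ids[i])
          if (pLoss > 0 && any(startsWith(g$tok, "wgd")) &&
              stats::runif(1) < pLoss) { keep[i] <- FALSE; next }
          if (pDup > 0 && stats::runif(1) < pDup) {
            counter <<- counter + 1L
            tag <- sprintf("ssd%d", counter)
            dep <- g$dep; tok <- g$tok
            copy <- newGene(g$seq, g$fam, c(tok, paste0(tag, "#2")),
                            c(dep, depthEnd), g$strand)
            extra[[i]] <- copy
            g$tok <- c(tok, paste0(tag, "#1")); g$dep <- c(dep, depthEnd)
            assign(ids[i], g, envir = genes)
          }
        }
        out <- character(0)
        for (i in seq_along(ids)) {
          if (keep[i]) out <- c(out, ids[i])
          if (!is.null(extra[[i]])) out <- c(out, extra[[i]])
        }
        genome[[s]] <- out
      }
      genome <- genome[lengths(genome) > 0L]
    }
    genome
  }

  applySimWgd <- function(genome, eventId, retention, depthNow) {
    newScafs <- stats::setNames(vector("list", length(genome)),
                                paste0(names(genome), "_", eventId))
    for (s in names(genome)) {
      copies <- character(0)
      for (id in genome[[s]]) {
        if (stats::runif(1) < retention) {
          g <- getG(id)
          copy <- newGene(g$seq, g$fam, c(g$tok, paste0(eventId, "#2")),
                          c(g$dep, depthNow), g$strand)
          g$tok <- c(g$tok, paste0(eventId, "#1"))
          g$dep <- c(g$dep, depthNow)
          assign(id, g, envir = genes)
          copies <- c(copies, copy)
        }
      }
      newScafs[[paste0(s, "_", eventId)]] <- copies
    }
    c(genome, newScafs[lengths(newScafs) > 0L])
  }

  tipResults <- list()

  descend <- function(genome, node) {
    kids <- children[[as.character(node)]]
    for (ci in seq_along(kids)) {
      child <- kids[[ci]]
      ## independent copy of every gene lineage, tagged with the split
      gclone <- genome
      for (s in names(gclone)) {
        gclone[[s]] <- vapply(gclone[[s]], function(id) {
          g <- getG(id)
          newGene(g$seq, g$fam, c(g$tok, sprintf("sp%d#%d", node, ci)),
                  c(g$dep, rd[node]), g$strand)
        }, character(1), USE.NAMES = FALSE)
      }
      ## walk the edge, interleaving WGD events at their positions
      at <- rd[node]
      if (!is.null(pos)) {
        here <- which(pos$child == child)
        here <- here[order(pos$eventRootDist[here])]
        for (e in here) {
          gclone <- evolveGenome(gclone, pos$eventRootDist[e] - at,
                                 pos$eventRootDist[e])
          gclone <- applySimWgd(gclone, ev$event_id[e], ev$retention[e],
                                pos$eventRootDist[e])
          at <- pos$eventRootDist[e]
        }
      }
      gclone <- evolveGenome(gclone, rd[child] - at, rd[child])
      if (child <= ntip) {
        tipResults[[phy$tip.label[child]]] <<-
          list(genome = gclone, tipNode = child)
      } else {
        descend(gclone, child)
      }
    }
  }
  descend(genome0, ntip + 1L)

  ## ---- emission ---------------------------------------------------------
  genomeObjs <- list(); cds <- list(); geneRows <- list()
  info <- list()  # final id -> internal record + tip root distance
  for (sp in phy$tip.label) {
    res <- tipResults[[sp]]
    genome <- res$genome
    ## inversions on the tip genome
    if (config@nInversions > 0 && length(genome)) {
      sizes <- lengths(genome)
      for (i in seq_len(config@nInversions)) {
        s <- sample(rep(names(genome), sizes), 1L)
        k <- length(genome[[s]])
        ij <- sort(sample.int(k, 2L, replace = TRUE))
        win <- ij[1L]:ij[2L]
        genome[[s]][win] <- rev(genome[[s]][win])
        for (id in genome[[s]][win]) {
          g <- getG(id)
          g$strand <- if (g$strand == "+") "-" else "+"
          assign(id, g, envir = genes)
        }
      }
    }
    cnt <- 0L
    rows <- list()
    for (s in names(genome)) {
      for (r in seq_along(genome[[s]])) {
        cnt <- cnt + 1L
        fid <- sprintf("%s_g%04d", sp, cnt)
        g <- getG(genome[[s]][r])
        rows[[cnt]] <- data.frame(
          gene_id = fid, species = sp, family = g$fam,
          scaffold = paste(sp, s, sep = "_"), rank = r - 1L,
          strand = g$strand, stringsAsFactors = FALSE)
        cds[[fid]] <- .idxToString(g$seq)
        info[[fid]] <- list(fam = g$fam, tok = g$tok, dep = g$dep,
                            seq = g$seq, species = sp,
                            tipRoot = rd[res$tipNode])
      }
    }
    tab <- do.call(rbind, rows)
    geneRows[[sp]] <- tab
    genomeObjs[[sp]] <- SpeciesGenome(sp, tab[, c("gene_id", "scaffold",
                                                  "rank", "strand")])
  }
  genesAll <- do.call(rbind, geneRows)
  rownames(genesAll) <- NULL
  cds <- unlist(cds)

  ## ---- homology + truth -------------------------------------------------
  aaCache <- lapply(info, function(x) .translateCodons(x$seq))
  byFam <- split(names(info), vapply(info, function(x) x$fam, numeric(1)))
  hom <- list(); pairKs <- list(); anch <- list()
  diverge <- function(a, b) {
    ta <- info[[a]]$tok; tb <- info[[b]]$tok
    k <- 1L
    while (k <= length(ta) && k <= length(tb) && ta[k] == tb[k]) k <- k + 1L
    if (k > length(ta) || k > length(tb))
      stop("indistinguishable gene genealogies")  # cannot happen
    list(depth = info[[a]]$dep[k], token = ta[k])
  }
  for (members in byFam) {
    if (length(members) < 2L) next
    pr <- utils::combn(members, 2L)
    for (q in seq_len(ncol(pr))) {
      a <- pr[1L, q]; b <- pr[2L, q]
      dv <- diverge(a, b)
      trueKs <- (info[[a]]$tipRoot - dv$depth) + (info[[b]]$tipRoot - dv$depth)
      pairKs[[length(pairKs) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, true_ks = trueKs, stringsAsFactors = FALSE)
      if (info[[a]]$species == info[[b]]$species &&
          startsWith(dv$token, "wgd")) {
        anch[[length(anch) + 1L]] <- data.frame(
          gene_a = a, gene_b = b, species = info[[a]]$species,
          event_id = sub("#.*$", "", dv$token), true_ks = trueKs,
          stringsAsFactors = FALSE)
      }
      p <- mean(aaCache[[a]] != aaCache[[b]])
      bit <- (1 - p) * length(aaCache[[a]])
      eval <- max(10^(-bit / 10), 1e-180)
      hom[[length(hom) + 1L]] <- data.frame(
        gene_a = c(a, b), gene_b = c(b, a), bitscore = bit, evalue = eval,
        stringsAsFactors = FALSE)
    }
  }
  emptyPair <- data.frame(gene_a = character(0), gene_b = character(0),
                          stringsAsFactors = FALSE)
  truth <- new("GroundTruth",
    genes = genesAll,
    events = if (nrow(ev)) ev[, c("event_id", "branch", "age_ks", "retention")]
             else data.frame(event_id = character(0), branch = character(0),
                             age_ks = numeric(0), retention = numeric(0)),
    anchors = if (length(anch)) do.call(rbind, anch)
              else cbind(emptyPair, species = character(0),
                         event_id = character(0), true_ks = numeric(0)),
    pairKs = if (length(pairKs)) do.call(rbind, pairKs)
             else cbind(emptyPair, true_ks = numeric(0)),
    nCapped = capped)
  list(genomes = genomeObjs, cds = cds,
       homology = if (length(hom)) do.call(rbind, hom)
                  else cbind(emptyPair, bitscore = numeric(0),
                             evalue = numeric(0)),
       speciesTree = phy, truth = truth, config = config)
}
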