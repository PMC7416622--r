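## Central S4 containers.

#' SpeciesGenome: ordered gene ranks per scaffold for one species
#'
#' Holds the gene order of one genome as 0-based ranks along scaffolds; base
#' pair coordinates are discarded after ranking because co-linearity analysis
#' operates on gene order only. Strand is stored for dot-plot orientation but
#' does not enter chaining scores.
#'
#' @slot species single species label.
#' @slot genes data.frame with columns \code{gene_id}, \code{scaffold},
#'   \code{rank} (0-based, gapless within scaffold), \code{strand}
#'   (\code{"+"}/\code{"-"}).
#' @exportClass SpeciesGenome
setClass("SpeciesGenome",
  representation(species = "character", genes = "data.frame"))

setValidity("SpeciesGenome", function(object) {
  g <- object@genes
  msg <- character()
  if (length(object@species) != 1L) msg <- c(msg, "species must be a single label")
  need <- c("gene_id", "scaffold", "rank", "strand")
  if (!all(need %in% names(g))) {
    return(paste("genes must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(g$gene_id)) {
    dup <- g$gene_id[duplicated(g$gene_id)][1L]
    msg <- c(msg, sprintf("duplicate gene_id '%s'", dup))
  }
  if (nrow(g)) {
    bad <- vapply(split(g$rank, g$scaffold), function(r) {
      !identical(sort(r), as.numeric(seq_along(r) - 1)) &&
        !identical(sort(as.integer(r)), seq_along(r) - 1L)
    }, logical(1))
    if (any(bad)) {
      msg <- c(msg, sprintf("ranks on scaffold '%s' are not 0..k-1",
                            names(bad)[bad][1L]))
    }
    if (!all(g$strand %in% c("+", "-"))) msg <- c(msg, "strand must be '+' or '-'")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a SpeciesGenome
#'
#' @param species species label.
#' @param genes data.frame with columns \code{gene_id}, \code{scaffold},
#'   \code{rank}, \code{strand}. Rows are re-ordered by scaffold then rank.
#' @return A \linkS4class{SpeciesGenome}.
#' @export
SpeciesGenome <- function(species, genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$rank <- as.integer(genes$rank)
  if (nrow(genes)) {
    genes <- genes[order(genes$scaffold, genes$rank), , drop = FALSE]
    rownames(genes) <- NULL
  }
  new("SpeciesGenome", species = as.character(species), genes = genes)
}

#' @describeIn SpeciesGenome species label accessor
#' @param object,x a \code{SpeciesGenome}.
#' @export
speciesId <- function(object) object@species

#' @describeIn SpeciesGenome gene table accessor
#' @export
geneTable <- function(object) object@genes

#' @describeIn SpeciesGenome number of genes
#' @export
nGenes <- function(object) nrow(object@genes)

setMethod("show", "SpeciesGenome", function(object) {
  cat(sprintf("SpeciesGenome '%s': %d genes on %d scaffolds\n",
              object@species, nrow(object@genes),
              length(unique(object@genes$scaffold))))
})

#' KsDistribution: (weighted) Ks age distribution
#'
#' One row per retained gene pair. For paranome distributions each pair carries
#' the redundancy-correcting weight 1/m of its duplication node so that every
#' duplication event contributes total mass one; ortholog and anchor
#' distributions carry unit weights.
#'
#' @slot entries data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{ks}, \code{weight}, \code{node_id}, \code{subfamily_id}.
#' @slot source one of \code{"paranome"}, \code{"anchors"}, \code{"orthologs"}.
#' @exportClass KsDistribution
setClass("KsDistribution",
  representation(entries = "data.frame", source = "character"))

setValidity("KsDistribution", function(object) {
  need <- c("gene_a", "gene_b", "ks", "weight")
  if (!all(need %in% names(object@entries)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (!object@source %in% c("paranome", "anchors", "orthologs"))
    return("source must be paranome, anchors or orthologs")
  w <- object@entries$weight
  if (length(w) && any(!is.na(w) & (w <= 0 | w > 1)))
    return("weights must lie in (0, 1]")
  TRUE
})

#' Construct a KsDistribution
#'
#' @param entries data.frame with at least \code{gene_a}, \code{gene_b},
#'   \code{ks}, \code{weight}; \code{node_id}/\code{subfamily_id} added as NA
#'   when absent.
#' @param source distribution provenance tag.
#' @return A \linkS4class{KsDistribution}.
#' @export
KsDistribution <- function(entries, source = c("paranome", "anchors", "orthologs")) {
  source <- match.arg(source)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (is.null(entries$node_id)) entries$node_id <- NA_character_
  if (is.null(entries$subfamily_id)) entries$subfamily_id <- NA_character_
  rownames(entries) <- NULL
  new("KsDistribution", entries = entries, source = source)
}

#' @describeIn KsDistribution entry table accessor
#' @param object a \code{KsDistribution}.
#' @export
ksEntries <- function(object) object@entries

#' @describeIn KsDistribution provenance tag accessor
#' @export
ksSource <- function(object) object@source

setMethod("show", "KsDistribution", function(object) {
  e <- object@entries
  fin <- e$ks[is.finite(e$ks)]
  cat(sprintf("KsDistribution (%s): %d entries, total mass %.2f%s\n",
              object@source, nrow(e), sum(e$weight, na.rm = TRUE),
              if (length(fin)) sprintf(", median Ks %.3f", stats::median(fin)) else ""))
})

#' CollinearSegmentSet: chained co-linear segments and their anchor pairs
#'
#' @slot segments data.frame with one row per segment: \code{segment_id},
#'   \code{scaffold_a}, \code{scaffold_b}, \code{direction}
#'   (\code{"forward"}/\code{"inverted"}), \code{n_anchors}, \code{score},
#'   \code{a_start}, \code{a_end}, \code{b_start}, \code{b_end} (closed rank
#'   intervals).
#' @slot anchors data.frame with one row per anchor pair: \code{segment_id},
#'   \code{gene_a}, \code{gene_b}, \code{rank_a}, \code{rank_b}.
#' @slot self logical; TRUE for a genome self-comparison (identity diagonal
#'   masked, unordered segment pairs reported once).
#' @exportClass CollinearSegmentSet
setClass("CollinearSegmentSet",
  representation(segments = "data.frame", anchors = "data.frame", self = "logical"))

setValidity("CollinearSegmentSet", function(object) {
  s <- object@segments
  need <- c("segment_id", "scaffold_a", "scaffold_b", "direction", "n_anchors",
            "score", "a_start", "a_end", "b_start", "b_end")
  if (!all(need %in% names(s)))
    return(paste("segments must have columns", paste(need, collapse = ", ")))
  a <- object@anchors
  if (!all(c("segment_id", "gene_a", "gene_b", "rank_a", "rank_b") %in% names(a)))
    return("anchors must have columns segment_id, gene_a, gene_b, rank_a, rank_b")
  for (sid in s$segment_id) {
    aa <- a[a$segment_id == sid, , drop = FALSE]
    aa <- aa[order(aa$rank_a), , drop = FALSE]
    if (any(diff(aa$rank_a) <= 0)) return(sprintf("segment %s: rank_a not strictly increasing", sid))
    d <- diff(aa$rank_b)
    dir <- s$direction[s$segment_id == sid]
    if (nrow(aa) > 1L) {
      if (dir == "forward" && any(d <= 0)) return(sprintf("segment %s: rank_b not strictly increasing", sid))
      if (dir == "inverted" && any(d >= 0)) return(sprintf("segment %s: rank_b not strictly decreasing", sid))
    }
  }
  TRUE
})

#' @describeIn CollinearSegmentSet segment table accessor
#' @param object a \code{CollinearSegmentSet}.
#' @export
segmentTable <- function(object) object@segments

#' @describeIn CollinearSegmentSet anchor pair table accessor
#' @export
anchorPairs <- function(object) object@anchors

setMethod("show", "CollinearSegmentSet", function(object) {
  cat(sprintf("CollinearSegmentSet: %d segments, %d anchor pairs%s\n",
              nrow(object@segments), nrow(object@anchors),
              if (isTRUE(object@self)) " (self-comparison)" else ""))
})

#' PipelineConfig: tunable thresholds of the WGD inference pipeline
#'
#' Defaults follow common practice for paranome/anchor analyses: a stringent
#' within-genome homology cutoff (1e-10), a milder cross-species cutoff (1e-5),
#' subfamily splitting and anchor filtering at Ks = 5 (beyond which synonymous
#' distance estimates saturate), a c-score floor of 0.5, a minimum of 5 anchor
#' pairs per co-linear segment (presets 5/10/15 for fragmented to
#' chromosome-level genomes), a WGD-peak window of [0.6, 1.4], a 300-gene cap
#' on families used for placement, bootstrap support thresholds of 50/80 and a
#' 90 percent percentile bootstrap CI.
#'
#' @slot paranomeEvalueCutoff,crossSpeciesEvalueCutoff E-value cutoffs.
#' @slot subfamilyMaxKs Ks ceiling for subfamily splitting / anchor filtering.
#' @slot cscoreMin minimum c-score retained.
#' @slot minAnchorPairs minimum anchors per reported segment.
#' @slot peakWindow numeric length-2 closed Ks interval around the WGD peak.
#' @slot placementMaxFamilySize largest family used for gene-tree placement.
#' @slot supportThresholds bootstrap percentage thresholds for event counting.
#' @slot kdeBandwidth bandwidth rule (\code{"silverman"}) or a fixed number.
#' @slot bootstrapReps bootstrap replicates for peak CIs and gene trees.
#' @slot ciCoverage percentile CI coverage in (0,1).
#' @slot rngSeed integer seed recorded for reproducibility.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    paranomeEvalueCutoff = "numeric", crossSpeciesEvalueCutoff = "numeric",
    subfamilyMaxKs = "numeric", cscoreMin = "numeric",
    minAnchorPairs = "numeric", peakWindow = "numeric",
    placementMaxFamilySize = "numeric", supportThresholds = "numeric",
    kdeBandwidth = "ANY", bootstrapReps = "numeric", ciCoverage = "numeric",
    rngSeed = "numeric"),
  prototype(
    paranomeEvalueCutoff = 1e-10, crossSpeciesEvalueCutoff = 1e-5,
    subfamilyMaxKs = 5, cscoreMin = 0.5, minAnchorPairs = 5,
    peakWindow = c(0.6, 1.4), placementMaxFamilySize = 300,
    supportThresholds = c(50, 80), kdeBandwidth = "silverman",
    bootstrapReps = 200, ciCoverage = 0.90, rngSeed = 1))

setValidity("PipelineConfig", function(object) {
  if (object@paranomeEvalueCutoff <= 0 || object@crossSpeciesEvalueCutoff <= 0)
    return("E-value cutoffs must be positive")
  if (object@subfamilyMaxKs <= 0) return("subfamilyMaxKs must be positive")
  if (length(object@peakWindow) != 2L || object@peakWindow[1] >= object@peakWindow[2])
    return("peakWindow must be (lo, hi) with lo < hi")
  if (object@ciCoverage <= 0 || object@ciCoverage >= 1)
    return("ciCoverage must lie in (0,1)")
  TRUE
})

#' Construct a PipelineConfig
#'
#' @param ... slot overrides, e.g. \code{minAnchorPairs = 15}.
#' @return A \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(...) new("PipelineConfig", ...)

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (s in methods::slotNames(object))
    cat(sprintf("  %s: %s\n", s, paste(format(slot(object, s)), collapse = ", ")))
})
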