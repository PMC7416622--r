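## Readers/writers for the standard formats the pipeline touches. All readers
## are deterministic given file bytes; gene ranks are assigned after sorting,
## so input row order never matters.

#' Read a gene map into SpeciesGenome objects
#'
#' Reads gene positions per scaffold and assigns 0-based gene-order ranks.
#' Genes on each scaffold are sorted by start coordinate, ties broken by
#' gene id; base-pair coordinates are discarded after ranking (downstream
#' co-linearity works on gene order only).
#'
#' @param path file path.
#' @param format \code{"tsv"} (columns \code{species}, \code{gene_id},
#'   \code{scaffold}, \code{start}, \code{end}, \code{strand}, with header) or
#'   \code{"gff3"} (gene features; 1-based inclusive coordinates; requires the
#'   rtracklayer package).
#' @param species for GFF3 input, the species label to assign; for TSV input,
#'   an optional subset of species to keep.
#' @return A named list of \linkS4class{SpeciesGenome} objects, one per
#'   species present.
#' @export
readGeneMap <- function(path, format = c("tsv", "gff3"), species = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "tsv") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
    need <- c("species", "gene_id", "scaffold", "start", "end", "strand")
    if (!all(need %in% names(d)))
      stop(sprintf("gene map must have columns: %s", paste(need, collapse = ", ")))
    if (!is.null(species)) d <- d[d$species %in% species, , drop = FALSE]
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GFF3 input requires the rtracklayer package")
    if (is.null(species) || length(species) != 1L)
      stop("GFF3 input requires a single 'species' label")
    gr <- rtracklayer::import(path)
    gd <- as.data.frame(gr[gr$type == "gene"])
    d <- data.frame(species = species,
                    gene_id = as.character(gd$ID),
                    scaffold = as.character(gd$seqnames),
                    start = gd$start,
                    end = gd$end,
                    strand = as.character(gd$strand),
                    stringsAsFactors = FALSE)
    d$strand[!d$strand %in% c("+", "-")] <- "+"
  }
  out <- lapply(split(d, d$species), function(ds) {
    if (anyDuplicated(ds$gene_id)) {
      dup <- ds$gene_id[duplicated(ds$gene_id)][1L]
      stop(sprintf("duplicate gene_id '%s' in species '%s'", dup, ds$species[1L]))
    }
    ds <- ds[order(ds$scaffold, ds$start, ds$gene_id), , drop = FALSE]
    rank <- unlist(lapply(split(seq_len(nrow(ds)), ds$scaffold),
                          function(i) seq_along(i) - 1L), use.names = FALSE)
    ## split() groups by scaffold in sorted order, matching the row sort
    SpeciesGenome(ds$species[1L],
                  data.frame(gene_id = ds$gene_id, scaffold = ds$scaffold,
                             rank = rank, strand = ds$strand,
                             stringsAsFactors = FALSE))
  })
  out
}

#' Read a tabular homology (similarity) table
#'
#' Accepts a BLAST outfmt-6-like table with columns query, subject, bitscore,
#' E-value (headerless, or with a header whose first column is
#' \code{qseqid}/\code{query}/\code{gene_a}). Self-hits are removed and edges
#' above the E-value cutoff dropped; the two directions (a,b) and (b,a) are
#' kept as separate rows because reciprocal-best-hit analysis needs
#' directionality.
#'
#' @param path file path.
#' @param evalueCutoff keep edges with \code{evalue <= evalueCutoff}.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{bitscore}, \code{evalue}.
#' @export
readHomologyTable <- function(path, evalueCutoff = Inf) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("^(qseqid|query|gene_a)\\b", first)
  d <- utils::read.table(path, header = hasHeader, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character", NA, NA))
  if (ncol(d) < 4L) stop("homology table needs >= 4 columns: query, subject, bitscore, evalue")
  d <- d[, 1:4]
  names(d) <- c("gene_a", "gene_b", "bitscore", "evalue")
  for (col in c("bitscore", "evalue")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L] + as.integer(hasHeader)
      stop(sprintf("non-numeric %s at line %d of %s", col, bad, path))
    }
    d[[col]] <- v
  }
  d <- d[d$gene_a != d$gene_b & d$evalue <= evalueCutoff, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read a rooted species tree from Newick
#'
#' Wraps \code{ape::read.tree} and validates that tip labels are unique.
#' Internal nodes receive stable identifiers through
#' \code{\link{speciesNodeId}} (the sorted set of descendant tip labels), so
#' placements are reproducible across runs regardless of node numbering.
#'
#' @param path Newick file.
#' @return An \code{ape} \code{phylo} object.
#' @export
readSpeciesTree <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop(sprintf("could not parse Newick in %s", path))
  if (anyDuplicated(tr$tip.label))
    stop(sprintf("duplicate tip label '%s'",
                 tr$tip.label[duplicated(tr$tip.label)][1L]))
  tr
}

#' Stable species-tree node identifier
#'
#' The identifier of a node is the sorted, "|"-joined set of its descendant
#' tip labels (a tip's id is its label). Branches are written
#' \code{parent_id -> child_id}.
#'
#' @param tree a \code{phylo} object.
#' @param node internal node or tip number(s) in \code{tree}; defaults to all
#'   nodes.
#' @return character vector of node ids.
#' @export
speciesNodeId <- function(tree, node = seq_len(ape::Ntip(tree) + tree$Nnode)) {
  ntip <- ape::Ntip(tree)
  vapply(node, function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    tips <- ape::extract.clade(tree, v)$tip.label
    paste(sort(tips), collapse = "|")
  }, character(1))
}

#' Write a TSV table
#'
#' @param records data.frame to write.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write coding sequences as FASTA
#'
#' @param cds named character vector or \code{DNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCdsFasta <- function(cds, path) {
  cds <- .asCdsVector(cds)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path)
  invisible(path)
}

#' Read coding sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readCdsFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
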