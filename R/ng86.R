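## Nei-Gojobori (1986) synonymous/nonsynonymous divergence with Jukes-Cantor
## correction. Codon-level quantities are precomputed once into lookup tables:
## per-codon synonymous site counts and, for every ordered codon pair, the
## synonymous/nonsynonymous difference counts averaged over all shortest
## mutational pathways (pathways through stop codons excluded; codon pairs with
## every pathway blocked are skipped entirely, i.e. removed from both the
## difference and the site tallies).

.ng86env <- new.env(parent = emptyenv())

.ngBases <- c("A", "C", "G", "T")

.ngPerms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

.ng86Tables <- function() {
  if (!is.null(.ng86env$SdTab)) return(invisible(.ng86env))
  codons <- apply(expand.grid(.ngBases, .ngBases, .ngBases,
                              stringsAsFactors = FALSE)[, 3:1], 1L,
                  paste0, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  isStop <- aa == "*"
  codonMat <- do.call(rbind, strsplit(codons, ""))
  codonIndex <- function(b) ((match(b[1], .ngBases) - 1L) * 16L +
                             (match(b[2], .ngBases) - 1L) * 4L +
                              match(b[3], .ngBases))

  ## synonymous site fractions per codon: each of the 9 single-base changes
  ## contributes 1/3 to S if it preserves the amino acid; changes into stop
  ## codons count as nonsynonymous
  siteS <- rep(NA_real_, 64L)
  for (i in seq_len(64L)) {
    if (isStop[i]) next
    s <- 0
    for (p in 1:3) for (b in .ngBases) {
      if (b == codonMat[i, p]) next
      alt <- codonMat[i, ]; alt[p] <- b
      j <- codonIndex(alt)
      if (!isStop[j] && aa[j] == aa[i]) s <- s + 1/3
    }
    siteS[i] <- s
  }

  ## pathway-averaged difference counts for ordered codon pairs
  SdTab <- matrix(NA_real_, 64L, 64L)
  NdTab <- matrix(NA_real_, 64L, 64L)
  for (i in seq_len(64L)) {
    if (isStop[i]) next
    SdTab[i, i] <- 0; NdTab[i, i] <- 0
    for (j in seq_len(64L)) {
      if (i == j || isStop[j]) next
      diffPos <- which(codonMat[i, ] != codonMat[j, ])
      d <- length(diffPos)
      syns <- numeric(0)
      for (perm in .ngPerms[[as.character(d)]]) {
        cur <- codonMat[i, ]; syn <- 0; ok <- TRUE
        for (step in perm) {
          p <- diffPos[step]
          nxt <- cur; nxt[p] <- codonMat[j, p]
          k0 <- codonIndex(cur); k1 <- codonIndex(nxt)
          if (isStop[k1]) { ok <- FALSE; break }
          if (aa[k1] == aa[k0]) syn <- syn + 1
          cur <- nxt
        }
        if (ok) syns <- c(syns, syn)
      }
      if (length(syns)) {
        SdTab[i, j] <- mean(syns)
        NdTab[i, j] <- d - mean(syns)
      }
    }
  }
  .ng86env$codons <- codons
  .ng86env$aa <- aa
  .ng86env$isStop <- isStop
  .ng86env$siteS <- siteS
  .ng86env$SdTab <- SdTab
  .ng86env$NdTab <- NdTab
  invisible(.ng86env)
}

## character DNA string -> vector of codon indices (1..64); NA for codons with
## ambiguous bases. A trailing stop codon is dropped; internal stops error.
.codonIndices <- function(cds, id = "sequence") {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop(sprintf("%s: length %d is not a multiple of 3", id, n))
  if (n < 3L) stop(sprintf("%s: fewer than one codon", id))
  b <- match(strsplit(cds, "")[[1L]], .ngBases)
  m <- matrix(b, nrow = 3L)
  idx <- (m[1L, ] - 1L) * 16L + (m[2L, ] - 1L) * 4L + m[3L, ]
  tabs <- .ng86Tables()
  stops <- which(!is.na(idx) & tabs$isStop[idx])
  if (length(stops)) {
    if (length(stops) == 1L && stops == length(idx)) {
      idx <- idx[-length(idx)]
    } else {
      stop(sprintf("%s: internal stop codon at codon %d", id, stops[1L]))
    }
  }
  idx
}

#' NG86 synonymous and nonsynonymous site counts
#'
#' Counts fractional synonymous (S) and nonsynonymous (N) sites of a coding
#' sequence under the standard genetic code: each of the three possible
#' single-base changes at a codon position contributes 1/3 of a synonymous
#' site if it preserves the amino acid; changes creating stop codons count as
#' nonsynonymous. S + N equals three times the codon count.
#'
#' @param cds coding sequence (character or \code{DNAString}); length must be
#'   a multiple of three with no internal stop codons (a trailing stop codon
#'   is ignored). Codons containing ambiguous bases are excluded.
#' @return Named numeric vector \code{c(S, N)}.
#' @examples
#' ng86Sites("GGG")  # S = 1, N = 2
#' @export
ng86Sites <- function(cds) {
  tabs <- .ng86Tables()
  idx <- .codonIndices(cds)
  idx <- idx[!is.na(idx)]
  S <- sum(tabs$siteS[idx])
  c(S = S, N = 3 * length(idx) - S)
}

#' NG86 synonymous and nonsynonymous difference counts
#'
#' For each differing codon pair, difference counts are averaged over all
#' shortest mutational pathways (1, 2 or 6 orderings of the changed
#' positions); pathways passing through a stop codon are excluded from the
#' average, and codon pairs whose pathways are all blocked are skipped.
#'
#' @param cdsA,cdsB equal-length coding sequences. Codon positions where
#'   either sequence is ambiguous are skipped pairwise.
#' @return Named numeric vector \code{c(Sd, Nd)}.
#' @examples
#' ng86Differences("TTT", "TTC")  # one synonymous difference
#' @export
ng86Differences <- function(cdsA, cdsB) {
  tabs <- .ng86Tables()
  ia <- .codonIndices(cdsA, "cdsA")
  ib <- .codonIndices(cdsB, "cdsB")
  if (length(ia) != length(ib))
    stop(sprintf("sequence lengths differ: %d vs %d codons", length(ia), length(ib)))
  keep <- !is.na(ia) & !is.na(ib)
  sd <- tabs$SdTab[cbind(ia[keep], ib[keep])]
  nd <- tabs$NdTab[cbind(ia[keep], ib[keep])]
  ok <- !is.na(sd)
  c(Sd = sum(sd[ok]), Nd = sum(nd[ok]))
}

## core computation on codon-index vectors (used by ksPair and ksPairwise)
.ksFromIndices <- function(ia, ib) {
  tabs <- .ng86env
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  sd <- tabs$SdTab[cbind(ia, ib)]
  ok <- !is.na(sd)
  ia <- ia[ok]; ib <- ib[ok]
  Sd <- sum(sd[ok])
  Nd <- sum(tabs$NdTab[cbind(ia, ib)])
  n <- length(ia)
  Ssites <- (sum(tabs$siteS[ia]) + sum(tabs$siteS[ib])) / 2
  Nsites <- 3 * n - Ssites
  pS <- if (Ssites > 0) Sd / Ssites else NA_real_
  pN <- if (Nsites > 0) Nd / Nsites else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    arg <- 1 - 4 * p / 3
    if (arg <= 0) Inf else -0.75 * log(arg)
  }
  ks <- jc(pS); ka <- jc(pN)
  data.frame(ks = ks, ka = ka, pS = pS, pN = pN,
             S_sites = Ssites, N_sites = Nsites, Sd = Sd, Nd = Nd,
             n_codons = n,
             saturated = (is.na(pS) || !is.finite(ks) ||
                          (!is.na(pN) && !is.finite(ka))))
}

#' Pairwise Ks/Ka by NG86 counting with Jukes-Cantor correction
#'
#' Estimates synonymous (Ks) and nonsynonymous (Ka) substitutions per site
#' between two aligned coding sequences: proportions of differences
#' pS = Sd / mean(S_A, S_B) and pN = Nd / mean(N_A, N_B) are corrected for
#' multiple hits by the Jukes-Cantor formula -3/4 ln(1 - 4p/3). When the log
#' argument is non-positive the estimate is saturated and reported as
#' \code{Inf} with \code{saturated = TRUE}. NG86 mildly underestimates
#' divergence at high Ks relative to maximum-likelihood codon models; for
#' peak-location analyses in the Ks range of interest (roughly below 2) the
#' difference is immaterial.
#'
#' @inheritParams ng86Differences
#' @return One-row data.frame: \code{ks}, \code{ka}, \code{pS}, \code{pN},
#'   \code{S_sites}, \code{N_sites}, \code{Sd}, \code{Nd}, \code{n_codons},
#'   \code{saturated}.
#' @examples
#' ksPair("TTTAAAGGG", "TTCAAAGGG")$ks  # -0.75 * log(0.2)
#' @export
ksPair <- function(cdsA, cdsB) {
  .ng86Tables()
  ia <- .codonIndices(cdsA, "cdsA")
  ib <- .codonIndices(cdsB, "cdsB")
  if (length(ia) != length(ib))
    stop(sprintf("sequence lengths differ: %d vs %d codons", length(ia), length(ib)))
  .ksFromIndices(ia, ib)
}

#' Ks/Ka for many gene pairs
#'
#' Vectorised driver over a set of coding sequences; codon index vectors are
#' computed once per gene.
#'
#' @param cds named character vector or \code{DNAStringSet} of coding
#'   sequences.
#' @param pairs data.frame (or 2-column matrix) whose first two columns name
#'   the genes of each pair.
#' @return data.frame with \code{gene_a}, \code{gene_b} and the
#'   \code{\link{ksPair}} columns, one row per pair; pairs with a missing
#'   sequence are dropped with a warning.
#' @export
ksPairwise <- function(cds, pairs) {
  .ng86Tables()
  cds <- .asCdsVector(cds)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  ga <- as.character(pairs[[1L]]); gb <- as.character(pairs[[2L]])
  have <- ga %in% names(cds) & gb %in% names(cds)
  if (any(!have)) {
    warning(sprintf("%d pair(s) skipped: missing sequence", sum(!have)))
    ga <- ga[have]; gb <- gb[have]
  }
  genes <- unique(c(ga, gb))
  idxList <- lapply(genes, function(g) .codonIndices(cds[[g]], g))
  names(idxList) <- genes
  out <- vector("list", length(ga))
  for (k in seq_along(ga)) {
    ia <- idxList[[ga[k]]]; ib <- idxList[[gb[k]]]
    if (length(ia) != length(ib))
      stop(sprintf("pair (%s, %s): sequence lengths differ", ga[k], gb[k]))
    out[[k]] <- .ksFromIndices(ia, ib)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- .ksFromIndices(integer(0), integer(0))[0, ]
    return(cbind(data.frame(gene_a = character(0), gene_b = character(0)), res))
  }
  cbind(data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE), res)
}

.asCdsVector <- function(cds) {
  if (methods::is(cds, "DNAStringSet")) cds <- as.character(cds)
  if (is.list(cds)) cds <- unlist(cds)
  if (is.null(names(cds)) || anyNA(names(cds)) || any(names(cds) == ""))
    stop("coding sequences must be named by gene id")
  cds
}

## translate a coding sequence to an amino-acid character vector (internal;
## used for protein-distance proxies and gene-tree distances)
.translateCodons <- function(idx) {
  tabs <- .ng86Tables()
  out <- rep(NA_character_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- tabs$aa[idx[ok]]
  out
}
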