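## Weighted Gaussian KDE peak location and percentile-bootstrap confidence
## intervals for WGD age estimates.

## weighted Silverman rule-of-thumb bandwidth; n replaced by the effective
## sample size (sum w)^2 / sum w^2
.silvermanBw <- function(values, weights) {
  w <- weights / sum(weights)
  mu <- sum(w * values)
  sdw <- sqrt(sum(w * (values - mu)^2))
  qs <- .weightedQuantile(values, w, c(0.25, 0.75))
  iqr <- qs[2L] - qs[1L]
  neff <- 1 / sum(w^2)
  spread <- min(sdw, iqr / 1.34)
  if (!is.finite(spread) || spread <= 0) spread <- max(sdw, 1e-3)
  0.9 * spread * neff^(-1/5)
}

.weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1L]], numeric(1))
}

#' Weighted KDE peak of a Ks (or age) sample
#'
#' Gaussian kernel density with per-observation weights, evaluated on a fixed
#' grid of step \code{gridStep} spanning the data range (optionally restricted
#' to a window); the peak is the grid argmax. All local maxima are returned so
#' secondary peaks (e.g. remnants of older WGDs) can be inspected.
#'
#' @param values numeric sample (non-finite entries dropped).
#' @param weights per-observation weights (default: equal).
#' @param bandwidth \code{"silverman"} (weighted rule of thumb) or a positive
#'   number.
#' @param gridStep evaluation grid step (default 0.01).
#' @param window optional length-2 closed interval restricting the peak
#'   search.
#' @return List with \code{peak}, \code{bandwidth}, \code{grid},
#'   \code{density}, and \code{modes} (data.frame of all local maxima, ordered
#'   by decreasing density).
#' @export
kdePeak <- function(values, weights = NULL, bandwidth = "silverman",
                    gridStep = 0.01, window = NULL) {
  keep <- is.finite(values)
  values <- values[keep]
  if (is.null(weights)) weights <- rep(1, length(values)) else {
    weights <- weights[keep]
  }
  if (length(values) < 10L)
    stop("kdePeak needs at least 10 finite values; provide more data")
  w <- weights / sum(weights)
  bw <- if (identical(bandwidth, "silverman")) .silvermanBw(values, w)
        else as.numeric(bandwidth)
  lo <- min(values); hi <- max(values)
  if (!is.null(window)) { lo <- max(lo, window[1L]); hi <- min(hi, window[2L]) }
  if (bw <= 0 || !is.finite(bw) || hi <= lo) {
    ## degenerate sample (zero spread): peak at the weighted mode
    peak <- values[which.max(w)]
    return(list(peak = peak, bandwidth = max(bw, 0), grid = peak,
                density = Inf,
                modes = data.frame(location = peak, density = Inf)))
  }
  grid <- seq(lo, hi, by = gridStep)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  ## dens[g] = sum_i w_i K_bw(g - x_i), computed as one matrix product
  dens <- as.vector(crossprod(stats::dnorm(outer(values, grid, "-"),
                                           sd = bw), w))
  peakIdx <- which.max(dens)
  isMax <- vapply(seq_along(grid), function(i) {
    l <- if (i > 1L) dens[i - 1L] else -Inf
    r <- if (i < length(grid)) dens[i + 1L] else -Inf
    dens[i] >= l && dens[i] >= r
  }, logical(1))
  modes <- data.frame(location = grid[isMax], density = dens[isMax])
  modes <- modes[order(-modes$density), , drop = FALSE]
  rownames(modes) <- NULL
  list(peak = grid[peakIdx], bandwidth = bw, grid = grid, density = dens,
       modes = modes)
}

#' Bootstrap percentile confidence interval of a KDE peak
#'
#' Resamples the observations with replacement (their weights travel with
#' them), relocates the KDE peak in each replicate and reports the percentile
#' interval of the replicate peaks. Deterministic given the RNG seed.
#'
#' @inheritParams kdePeak
#' @param B number of bootstrap replicates (>= 100).
#' @param coverage interval coverage in (0,1), default 0.90.
#' @return List with \code{peak} (full-sample peak), \code{lo}, \code{hi},
#'   \code{coverage} and \code{replicates} (the B replicate peak locations).
#' @export
bootstrapPeakCi <- function(values, weights = NULL, B = 200, coverage = 0.90,
                            bandwidth = "silverman", gridStep = 0.01,
                            window = NULL) {
  if (B < 100L) stop("B must be at least 100")
  keep <- is.finite(values)
  values <- values[keep]
  if (is.null(weights)) weights <- rep(1, length(values)) else weights <- weights[keep]
  if (length(values) < 10L)
    stop("bootstrapPeakCi needs at least 10 finite values; provide more data")
  full <- kdePeak(values, weights, bandwidth, gridStep, window)
  n <- length(values)
  reps <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    kdePeak(values[i], weights[i], bandwidth, gridStep, window)$peak
  }, numeric(1))
  alpha <- (1 - coverage) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  list(peak = full$peak, lo = ci[1L], hi = ci[2L], coverage = coverage,
       replicates = reps)
}

#' Restrict Ks entries to a closed window
#'
#' Keeps entries with \code{lo <= ks <= hi} (both boundaries included), the
#' convention used to select pairs under a WGD peak (default window 0.6-1.4).
#'
#' @param entries data.frame with a \code{ks} column, or a
#'   \linkS4class{KsDistribution}.
#' @param lo,hi closed interval bounds, \code{lo < hi}.
#' @return Object of the same type as \code{entries}, filtered.
#' @export
selectWindow <- function(entries, lo = 0.6, hi = 1.4) {
  stopifnot(lo < hi)
  if (methods::is(entries, "KsDistribution")) {
    e <- entries@entries
    e <- e[is.finite(e$ks) & e$ks >= lo & e$ks <= hi, , drop = FALSE]
    rownames(e) <- NULL
    return(KsDistribution(e, source = entries@source))
  }
  e <- entries[is.finite(entries$ks) & entries$ks >= lo & entries$ks <= hi, ,
               drop = FALSE]
  rownames(e) <- NULL
  e
}
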