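## Channel events: per-channel contiguous supra-threshold runs.
## Returns a data.frame (channel, start, end), end inclusive, sorted by start.
.channelEvents <- function(raster) {
  res <- lapply(seq_len(nrow(raster@beyond)), function(ch) {
    runs <- .logicalRuns(raster@beyond[ch, ])
    if (nrow(runs) == 0) return(NULL)
    data.frame(channel = ch, start = runs[, 1], end = runs[, 2])
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(channel = integer(0), start = integer(0),
                      end = integer(0))
  out[order(out$start), , drop = FALSE]
}

#' Extract avalanches from an excursion raster
#'
#' An avalanche is a maximal run of consecutive samples in which at least one
#' channel is beyond threshold; it is preceded and followed by at least one
#' retained sample with no excursion on any channel. Runs abutting a mask
#' boundary or the first/last sample of the recording are discarded, since a
#' truncated avalanche would bias its size and duration.
#'
#' Size is computed per \code{sizeMode}: \code{"integrated"} sums
#' |z| / fs over all supra-threshold samples of all channels (units SD s,
#' comparable across sampling rates); \code{"sample_sum"} omits the 1/fs
#' factor (units SD).
#'
#' @param raster an \linkS4class{ExcursionRaster}
#' @param rec the z-scored \linkS4class{MultichannelRecording} the raster was
#'   computed from
#' @param sizeMode "integrated" (default) or "sample_sum"
#' @return an \linkS4class{AvalancheCatalog}
#' @export
extractAvalanches <- function(raster, rec,
                              sizeMode = c("integrated", "sample_sum")) {
  stopifnot(is(raster, "ExcursionRaster"), is(rec, "MultichannelRecording"))
  sizeMode <- match.arg(sizeMode)
  if (ncol(raster@beyond) != nSamples(rec) ||
      nrow(raster@beyond) != nChannels(rec) ||
      !identical(raster@mask, rec@mask))
    stop("raster and recording do not share the same grid")
  fs <- raster@fs
  nSamp <- ncol(raster@beyond)
  active <- colSums(raster@beyond) > 0
  runs <- .logicalRuns(active)
  emptyCat <- function() {
    new("AvalancheCatalog",
        avalanches = data.frame(onset_sample = integer(0),
                                offset_sample = integer(0),
                                onset_s = numeric(0), offset_s = numeric(0),
                                duration_s = numeric(0), size = numeric(0),
                                n_channels = integer(0)),
        fs = fs, theta = raster@theta, sizeMode = sizeMode,
        totalRetainedTime = sum(rec@mask) / fs)
  }
  if (nrow(runs) == 0) return(emptyCat())
  ## drop runs abutting recording edges or masked samples
  prevIdx <- runs[, 1] - 1L
  nextIdx <- runs[, 2] + 1L
  ok <- prevIdx >= 1L & nextIdx <= nSamp &
    raster@mask[pmax(prevIdx, 1L)] & raster@mask[pmin(nextIdx, nSamp)]
  runs <- runs[ok, , drop = FALSE]
  if (nrow(runs) == 0) return(emptyCat())

  ## per-sample size contribution, summed over channels
  contrib <- colSums(abs(rec@signal) * raster@beyond)
  if (sizeMode == "integrated") contrib <- contrib / fs
  cs <- c(0, cumsum(contrib))
  size <- cs[runs[, 2] + 1L] - cs[runs[, 1]]

  ## channels involved, via channel events assigned to runs by start sample
  ev <- .channelEvents(raster)
  nCh <- integer(nrow(runs))
  if (nrow(ev) > 0) {
    runOf <- findInterval(ev$start, runs[, 1])
    inRun <- runOf >= 1 & ev$start <= runs[pmax(runOf, 1L), 2]
    tab <- tapply(ev$channel[inRun], runOf[inRun],
                  function(ch) length(unique(ch)))
    nCh[as.integer(names(tab))] <- as.integer(tab)
  }
  av <- data.frame(
    onset_sample = runs[, 1], offset_sample = runs[, 2] + 1L,
    onset_s = rec@t0 + (runs[, 1] - 1L) / fs,
    offset_s = rec@t0 + runs[, 2] / fs,
    duration_s = (runs[, 2] - runs[, 1] + 1L) / fs,
    size = size, n_channels = nCh)
  new("AvalancheCatalog", avalanches = av, fs = fs, theta = raster@theta,
      sizeMode = sizeMode, totalRetainedTime = sum(rec@mask) / fs)
}

#' @describeIn estimateBranchingParameter raster-bin convention: channel
#'   events are assigned to consecutive bins of \code{binWidth} seconds from
#'   each avalanche onset, and the estimate is the mean over avalanches
#'   spanning at least two bins of (events starting in bin 2) /
#'   (events starting in bin 1).
#' @param raster the \linkS4class{ExcursionRaster} the catalog was extracted
#'   from
#' @param binWidth bin width in seconds (default 4 samples)
#' @export
setMethod("estimateBranchingParameter", "AvalancheCatalog",
          function(x, raster, binWidth = 4 / samplingRate(x), ...) {
  stopifnot(is(raster, "ExcursionRaster"))
  fs <- samplingRate(x)
  if (binWidth <= 1 / fs) stop("binWidth must exceed one sample")
  av <- avalanches(x)
  binSamples <- binWidth * fs
  spans2 <- (av$offset_sample - av$onset_sample) > binSamples
  if (!any(spans2))
    stop("no avalanche spans two bins; cannot estimate the branching parameter")
  ev <- .channelEvents(raster)
  idx <- which(spans2)
  starts <- sort(ev$start)
  countIn <- function(lo, hi) {
    ## number of event starts in [lo, hi], integer sample indices
    findInterval(hi + 0.5, starts) - findInterval(lo - 0.5, starts)
  }
  o <- av$onset_sample[idx]
  e <- av$offset_sample[idx] - 1L
  b1 <- countIn(o, pmin(e, o + ceiling(binSamples) - 1L))
  b2 <- countIn(o + ceiling(binSamples),
                pmin(e, o + 2L * ceiling(binSamples) - 1L))
  ratios <- b2 / b1
  list(sigmaHat = mean(ratios), binWidth = binWidth,
       nAvalanchesUsed = length(idx))
})

#' Subset a catalog by time intervals
#'
#' Keeps avalanches whose onset lies in any of the half-open intervals
#' [start_s, end_s); the catalog's total retained time becomes the length of
#' the interval union.
#'
#' @param catalog an \linkS4class{AvalancheCatalog}
#' @param intervals 2-column matrix or data.frame of (start_s, end_s)
#' @return the filtered \linkS4class{AvalancheCatalog}
#' @export
filterCatalogByIntervals <- function(catalog, intervals) {
  stopifnot(is(catalog, "AvalancheCatalog"))
  intervals <- .checkIntervals(intervals)
  if (nrow(intervals) == 0) stop("interval list must not be empty")
  av <- avalanches(catalog)
  keep <- rep(FALSE, nrow(av))
  for (i in seq_len(nrow(intervals)))
    keep <- keep | (av$onset_s >= intervals[i, 1] &
                      av$onset_s < intervals[i, 2])
  catalog@avalanches <- av[keep, , drop = FALSE]
  rownames(catalog@avalanches) <- NULL
  catalog@totalRetainedTime <- .intervalUnionLength(intervals)
  catalog
}
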