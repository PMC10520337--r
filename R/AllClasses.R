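#' @import methods
NULL

#' MultichannelRecording: a channels x samples signal with sampling metadata
#'
#' Container for a multichannel recording (EEG or surrogate). The signal is a
#' numeric matrix with one row per channel; \code{mask} marks retained samples
#' (FALSE = removed as artifact/wake). After \code{\link{zscoreNormalize}} each
#' channel has zero mean and unit SD over retained samples and
#' \code{isZScored(x)} is TRUE.
#'
#' @slot signal numeric matrix, channels x samples
#' @slot fs sampling rate in Hz
#' @slot channelLabels character vector of channel names
#' @slot mask logical vector, length = samples; TRUE = retained
#' @slot t0 time (s) of the first sample
#' @slot zscored logical scalar
#' @export
setClass("MultichannelRecording",
  representation(
    signal = "matrix",
    fs = "numeric",
    channelLabels = "character",
    mask = "logical",
    t0 = "numeric",
    zscored = "logical"
  ),
  prototype(t0 = 0, zscored = FALSE)
)

setValidity("MultichannelRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@signal)) msg <- c(msg, "signal must be numeric")
  if (length(object@fs) != 1L || is.na(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelLabels) != nrow(object@signal))
    msg <- c(msg, "channelLabels length must equal number of channels")
  if (length(object@mask) != ncol(object@signal))
    msg <- c(msg, "mask length must equal number of samples")
  if (anyNA(object@mask)) msg <- c(msg, "mask must not contain NA")
  if (length(object@zscored) != 1L) msg <- c(msg, "zscored must be a scalar")
  if (isTRUE(object@zscored) && any(object@mask)) {
    mu <- rowMeans(object@signal[, object@mask, drop = FALSE])
    if (max(abs(mu)) > 1e-6)
      msg <- c(msg, "zscored recording must have per-channel mean ~0 over retained samples")
  }
  if (length(msg)) msg else TRUE
})

#' ExcursionRaster: supra-threshold sample raster
#'
#' Logical channels x samples matrix, TRUE where |z| exceeds the threshold
#' theta on a retained sample.
#'
#' @slot beyond logical matrix, channels x samples
#' @slot theta threshold in SD units
#' @slot fs sampling rate in Hz
#' @slot mask logical retained-sample vector (copied from the recording)
#' @export
setClass("ExcursionRaster",
  representation(beyond = "matrix", theta = "numeric", fs = "numeric",
                 mask = "logical")
)

setValidity("ExcursionRaster", function(object) {
  msg <- character()
  if (!is.logical(object@beyond)) msg <- c(msg, "beyond must be logical")
  if (object@theta <= 0) msg <- c(msg, "theta must be > 0")
  if (length(object@mask) != ncol(object@beyond))
    msg <- c(msg, "mask length must equal number of samples")
  if (any(object@beyond[, !object@mask]))
    msg <- c(msg, "beyond must be FALSE on masked samples")
  if (length(msg)) msg else TRUE
})

#' AvalancheSample: ground-truth avalanches from a branching simulation
#'
#' Sizes are total activation counts, durations are generation counts
#' (the seed generation, Z0 = 1, is counted), and \code{generationCounts}
#' stores the per-generation activation counts of each avalanche.
#'
#' @slot sizes numeric vector of total activations per avalanche
#' @slot durations integer vector of generation counts
#' @slot generationCounts list of integer vectors, one per avalanche
#' @slot offspringMean the branching ratio used by the simulator
#' @slot dtStep seconds per generation, used when mapping to a time axis
#' @export
setClass("AvalancheSample",
  representation(sizes = "numeric", durations = "integer",
                 generationCounts = "list", offspringMean = "numeric",
                 dtStep = "numeric"),
  prototype(dtStep = 0.01)
)

setValidity("AvalancheSample", function(object) {
  msg <- character()
  n <- length(object@sizes)
  if (length(object@durations) != n || length(object@generationCounts) != n)
    msg <- c(msg, "sizes, durations and generationCounts must have equal length")
  if (n > 0) {
    if (any(object@durations < 1L)) msg <- c(msg, "durations must be >= 1")
    if (any(object@sizes < object@durations))
      msg <- c(msg, "each size must be >= its duration")
  }
  if (length(msg)) msg else TRUE
})

#' AvalancheCatalog: detected avalanches with sizes and durations
#'
#' Ordered, disjoint avalanches detected on a recording. The \code{avalanches}
#' slot is a data.frame with columns \code{onset_sample}, \code{offset_sample}
#' (half-open, 1-based), \code{onset_s}, \code{offset_s}, \code{duration_s},
#' \code{size} and \code{n_channels}.
#'
#' @slot avalanches data.frame, one row per avalanche
#' @slot fs sampling rate in Hz
#' @slot theta detection threshold in SD units
#' @slot sizeMode "integrated" (SD s) or "sample_sum" (SD)
#' @slot totalRetainedTime total retained (unmasked) time in seconds
#' @export
setClass("AvalancheCatalog",
  representation(avalanches = "data.frame", fs = "numeric", theta = "numeric",
                 sizeMode = "character", totalRetainedTime = "numeric")
)

setValidity("AvalancheCatalog", function(object) {
  msg <- character()
  av <- object@avalanches
  need <- c("onset_sample", "offset_sample", "onset_s", "offset_s",
            "duration_s", "size", "n_channels")
  if (!all(need %in% names(av)))
    msg <- c(msg, paste("avalanches must have columns:", paste(need, collapse = ", ")))
  else if (nrow(av) > 0) {
    if (any(av$offset_sample <= av$onset_sample))
      msg <- c(msg, "offset must exceed onset")
    if (is.unsorted(av$onset_sample))
      msg <- c(msg, "avalanches must be sorted by onset")
    if (nrow(av) > 1 && any(av$onset_sample[-1] < av$offset_sample[-nrow(av)]))
      msg <- c(msg, "avalanches must be disjoint")
    if (any(av$size <= 0)) msg <- c(msg, "sizes must be positive")
  }
  if (!object@sizeMode %in% c("integrated", "sample_sum"))
    msg <- c(msg, "sizeMode must be 'integrated' or 'sample_sum'")
  if (length(msg)) msg else TRUE
})

#' Hypnogram: 30-s epoch sleep-stage labels
#'
#' @slot epochStages character vector with values in W, N1, N2, N3, REM
#' @slot epochLength epoch length in seconds (30)
#' @slot startS time offset (s) of the first epoch
#' @export
setClass("Hypnogram",
  representation(epochStages = "character", epochLength = "numeric",
                 startS = "numeric"),
  prototype(epochLength = 30, startS = 0)
)

.STAGES <- c("W", "N1", "N2", "N3", "REM")

setValidity("Hypnogram", function(object) {
  msg <- character()
  bad <- setdiff(unique(object@epochStages), .STAGES)
  if (length(bad))
    msg <- c(msg, paste("unknown stage labels:", paste(bad, collapse = ", ")))
  if (object@epochLength != 30)
    msg <- c(msg, "epochLength must be 30 s")
  if (length(msg)) msg else TRUE
})

#' CapAnnotation: CAP phase intervals within NREM sleep
#'
#' Phases are stored as a data.frame with columns \code{onset_s},
#' \code{duration_s} and \code{label} (A1, A2, A3 or B). Durations outside
#' [2, 60] s are tolerated on load (with a warning) but flagged by validity
#' only if negative.
#'
#' @slot phases data.frame of phase intervals, sorted, non-overlapping
#' @export
setClass("CapAnnotation", representation(phases = "data.frame"))

.CAP_LABELS <- c("A1", "A2", "A3", "B")

setValidity("CapAnnotation", function(object) {
  msg <- character()
  ph <- object@phases
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(ph)))
    msg <- c(msg, paste("phases must have columns:", paste(need, collapse = ", ")))
  else if (nrow(ph) > 0) {
    if (any(ph$duration_s <= 0)) msg <- c(msg, "phase durations must be positive")
    bad <- setdiff(unique(ph$label), .CAP_LABELS)
    if (length(bad)) msg <- c(msg, paste("unknown phase labels:", paste(bad, collapse = ", ")))
    if (is.unsorted(ph$onset_s)) msg <- c(msg, "phases must be sorted by onset")
    if (nrow(ph) > 1) {
      ends <- ph$onset_s + ph$duration_s
      if (any(ph$onset_s[-1] < ends[-nrow(ph)] - 1e-9))
        msg <- c(msg, "phases must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PowerLawFit: truncated power-law maximum-likelihood fit
#'
#' @slot exponent fitted exponent (tau for sizes, alpha for durations)
#' @slot xmin,xmax fit range, same units as the sample
#' @slot nTail number of samples inside [xmin, xmax]
#' @slot ksD Kolmogorov-Smirnov distance between data and fit
#' @slot loglik maximized log-likelihood
#' @export
setClass("PowerLawFit",
  representation(exponent = "numeric", xmin = "numeric", xmax = "numeric",
                 nTail = "integer", ksD = "numeric", loglik = "numeric")
)

setValidity("PowerLawFit", function(object) {
  msg <- character()
  if (object@exponent <= 1) msg <- c(msg, "exponent must be > 1")
  if (object@ksD < 0 || object@ksD > 1) msg <- c(msg, "ksD must lie in [0, 1]")
  if (object@nTail < 10L) msg <- c(msg, "nTail must be >= 10")
  if (length(msg)) msg else TRUE
})

#' ScalingFit: mean-size-versus-duration scaling with optional crossover
#'
#' @slot kLow exponent below the crossover (or for the whole range)
#' @slot kHigh exponent above the crossover (NA when a single regime is fit)
#' @slot crossoverT regime split duration in the duration units used
#' @slot binnedCurve data.frame with per-bin mean duration and mean size
#' @export
setClass("ScalingFit",
  representation(kLow = "numeric", kHigh = "numeric", crossoverT = "numeric",
                 binnedCurve = "data.frame")
)

#' DensitySeries: sliding-window avalanche density
#'
#' @slot series data.frame with columns t, Fav, Nav, meanT, valid
#' @slot u0 window length in seconds
#' @slot stride window stride in seconds
#' @export
setClass("DensitySeries",
  representation(series = "data.frame", u0 = "numeric", stride = "numeric")
)

setValidity("DensitySeries", function(object) {
  msg <- character()
  s <- object@series
  need <- c("t", "Fav", "Nav", "meanT", "valid")
  if (!all(need %in% names(s)))
    msg <- c(msg, paste("series must have columns:", paste(need, collapse = ", ")))
  else if (nrow(s) > 0) {
    ok <- s$valid
    if (any(s$Fav[ok] < -1e-9 | s$Fav[ok] > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "Fav must lie in [0, 1] on valid windows")
  }
  if (object@u0 <= 0) msg <- c(msg, "u0 must be positive")
  if (length(msg)) msg else TRUE
})

#' BinaryIndicator: per-sample 0/1 feature series
#'
#' @slot values logical vector on the recording's sample grid (FALSE on
#'   masked samples)
#' @slot featureName feature label, e.g. "avalanche", "N3", "A1"
#' @slot mask logical retained-sample vector
#' @export
setClass("BinaryIndicator",
  representation(values = "logical", featureName = "character",
                 mask = "logical")
)

setValidity("BinaryIndicator", function(object) {
  msg <- character()
  if (length(object@values) != length(object@mask))
    msg <- c(msg, "values and mask must have equal length")
  else if (any(object@values & !object@mask))
    msg <- c(msg, "values must be FALSE on masked samples")
  if (length(msg)) msg else TRUE
})
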