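#' @include AllClasses.R
NULL

#' Number of channels
#' @param x a MultichannelRecording or ExcursionRaster
#' @return integer count
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of samples
#' @param x a MultichannelRecording or ExcursionRaster
#' @return integer count
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sampling rate in Hz
#' @param x an object with a sample grid
#' @return numeric scalar
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Signal matrix (channels x samples)
#' @param x a MultichannelRecording
#' @return numeric matrix
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' Retained-sample mask
#' @param x an object carrying a per-sample mask
#' @return logical vector
#' @export
setGeneric("retainedMask", function(x) standardGeneric("retainedMask"))

#' Channel labels
#' @param x a MultichannelRecording
#' @return character vector
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Has the recording been z-scored?
#' @param x a MultichannelRecording
#' @return logical scalar
#' @export
setGeneric("isZScored", function(x) standardGeneric("isZScored"))

#' Avalanche table of a catalog
#' @param x an AvalancheCatalog
#' @return data.frame with one row per avalanche
#' @export
setGeneric("avalanches", function(x) standardGeneric("avalanches"))

#' Avalanche sizes
#' @param x an AvalancheCatalog or AvalancheSample
#' @return numeric vector
#' @export
setGeneric("avalancheSizes", function(x) standardGeneric("avalancheSizes"))

#' Avalanche durations
#'
#' Seconds for an AvalancheCatalog; generations for an AvalancheSample.
#' @param x an AvalancheCatalog or AvalancheSample
#' @return numeric vector
#' @export
setGeneric("avalancheDurations", function(x) standardGeneric("avalancheDurations"))

#' Number of avalanches
#' @param x an AvalancheCatalog or AvalancheSample
#' @return integer count
#' @export
setGeneric("nAvalanches", function(x) standardGeneric("nAvalanches"))

#' Sleep-stage label sequence
#' @param x a Hypnogram
#' @return character vector of 30-s epoch labels
#' @export
setGeneric("epochStages", function(x) standardGeneric("epochStages"))

#' Total duration in seconds
#' @param x a Hypnogram or MultichannelRecording
#' @return numeric scalar
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' CAP phase table
#' @param x a CapAnnotation
#' @return data.frame with onset_s, duration_s, label
#' @export
setGeneric("capPhases", function(x) standardGeneric("capPhases"))

#' Estimate the branching parameter
#'
#' For an \code{AvalancheCatalog} the estimator follows the raster convention:
#' each avalanche is discretized into bins of \code{binWidth} seconds from its
#' onset, a channel-event is a contiguous supra-threshold run of one channel
#' assigned to the bin its start falls in, and the estimate is the mean over
#' avalanches spanning at least two bins of (events in bin 2)/(events in bin 1).
#'
#' For an \code{AvalancheSample} from \code{\link{simulateBranchingProcess}}
#' generations are the bins, with the seed as generation 0 (standard
#' Galton-Watson indexing): the estimate is the mean over avalanches lasting
#' at least two generations of Z2/Z1, the ratio of second- to first-generation
#' activations. This ratio is an unbiased estimator of the offspring mean.
#'
#' @param x an AvalancheCatalog or AvalancheSample
#' @param ... method-specific arguments (see
#'   \code{\link{estimateBranchingParameter,AvalancheCatalog-method}})
#' @return a list with \code{sigmaHat}, \code{binWidth} (NA for generations)
#'   and \code{nAvalanchesUsed}
#' @export
setGeneric("estimateBranchingParameter",
           function(x, ...) standardGeneric("estimateBranchingParameter"))

#' Fit the mean-size-versus-duration scaling law
#' @param x an AvalancheCatalog, AvalancheSample, or numeric durations
#' @param ... see \code{\link{sizeDurationScaling,numeric-method}}
#' @return a \linkS4class{ScalingFit}
#' @export
setGeneric("sizeDurationScaling",
           function(x, ...) standardGeneric("sizeDurationScaling"))
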