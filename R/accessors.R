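#' @include AllGenerics.R
NULL

#' @rdname nChannels
#' @export
setMethod("nChannels", "MultichannelRecording", function(x) nrow(x@signal))
#' @rdname nChannels
#' @export
setMethod("nChannels", "ExcursionRaster", function(x) nrow(x@beyond))

#' @rdname nSamples
#' @export
setMethod("nSamples", "MultichannelRecording", function(x) ncol(x@signal))
#' @rdname nSamples
#' @export
setMethod("nSamples", "ExcursionRaster", function(x) ncol(x@beyond))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "MultichannelRecording", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ExcursionRaster", function(x) x@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "AvalancheCatalog", function(x) x@fs)

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "MultichannelRecording", function(x) x@signal)

#' @rdname retainedMask
#' @export
setMethod("retainedMask", "MultichannelRecording", function(x) x@mask)
#' @rdname retainedMask
#' @export
setMethod("retainedMask", "ExcursionRaster", function(x) x@mask)

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "MultichannelRecording", function(x) x@channelLabels)

#' @rdname isZScored
#' @export
setMethod("isZScored", "MultichannelRecording", function(x) x@zscored)

#' @rdname avalanches
#' @export
setMethod("avalanches", "AvalancheCatalog", function(x) x@avalanches)

#' @rdname avalancheSizes
#' @export
setMethod("avalancheSizes", "AvalancheCatalog", function(x) x@avalanches$size)
#' @rdname avalancheSizes
#' @export
setMethod("avalancheSizes", "AvalancheSample", function(x) x@sizes)

#' @rdname avalancheDurations
#' @export
setMethod("avalancheDurations", "AvalancheCatalog",
          function(x) x@avalanches$duration_s)
#' @rdname avalancheDurations
#' @export
setMethod("avalancheDurations", "AvalancheSample",
          function(x) as.numeric(x@durations))

#' @rdname nAvalanches
#' @export
setMethod("nAvalanches", "AvalancheCatalog", function(x) nrow(x@avalanches))
#' @rdname nAvalanches
#' @export
setMethod("nAvalanches", "AvalancheSample", function(x) length(x@sizes))

#' @rdname epochStages
#' @export
setMethod("epochStages", "Hypnogram", function(x) x@epochStages)

#' @rdname totalDuration
#' @export
setMethod("totalDuration", "Hypnogram",
          function(x) length(x@epochStages) * x@epochLength)
#' @rdname totalDuration
#' @export
setMethod("totalDuration", "MultichannelRecording",
          function(x) ncol(x@signal) / x@fs)

#' @rdname capPhases
#' @export
setMethod("capPhases", "CapAnnotation", function(x) x@phases)

setMethod("show", "MultichannelRecording", function(object) {
  cat(sprintf("MultichannelRecording: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nChannels(object), nSamples(object), object@fs,
              nSamples(object) / object@fs))
  cat(sprintf("  retained samples: %d (%.1f%%); z-scored: %s\n",
              sum(object@mask), 100 * mean(object@mask),
              ifelse(object@zscored, "yes", "no")))
})

setMethod("show", "ExcursionRaster", function(object) {
  cat(sprintf("ExcursionRaster: %d x %d, theta = %g SD, %d supra-threshold cells\n",
              nrow(object@beyond), ncol(object@beyond), object@theta,
              sum(object@beyond)))
})

setMethod("show", "AvalancheSample", function(object) {
  n <- length(object@sizes)
  cat(sprintf("AvalancheSample: %d avalanche(s), offspring mean %g\n",
              n, object@offspringMean))
  if (n > 0)
    cat(sprintf("  mean size %.2f, mean duration %.2f generations\n",
                mean(object@sizes), mean(object@durations)))
})

setMethod("show", "AvalancheCatalog", function(object) {
  cat(sprintf("AvalancheCatalog: %d avalanche(s), theta = %g SD, size mode '%s'\n",
              nrow(object@avalanches), object@theta, object@sizeMode))
  if (nrow(object@avalanches) > 0)
    cat(sprintf("  total avalanche time %.2f s of %.2f s retained\n",
                sum(object@avalanches$duration_s), object@totalRetainedTime))
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@epochStages, levels = .STAGES))
  cat(sprintf("Hypnogram: %d epochs of %g s (%.1f min)\n",
              length(object@epochStages), object@epochLength,
              totalDuration(object) / 60))
  cat("  ", paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
})

setMethod("show", "CapAnnotation", function(object) {
  ph <- object@phases
  cat(sprintf("CapAnnotation: %d phase(s)", nrow(ph)))
  if (nrow(ph) > 0) {
    tab <- table(factor(ph$label, levels = .CAP_LABELS))
    cat(": ", paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "))
  }
  cat("\n")
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: exponent %.4f on [%g, %g], n = %d, KS D = %.4f\n",
              object@exponent, object@xmin, object@xmax, object@nTail,
              object@ksD))
})

setMethod("show", "ScalingFit", function(object) {
  cat(sprintf("ScalingFit: k = %.3f below T = %g", object@kLow, object@crossoverT))
  if (!is.na(object@kHigh)) cat(sprintf(", k = %.3f above", object@kHigh))
  cat(sprintf(" (%d bins)\n", nrow(object@binnedCurve)))
})

setMethod("show", "DensitySeries", function(object) {
  s <- object@series
  cat(sprintf("DensitySeries: %d windows (u0 = %g s, stride = %g s), %d valid\n",
              nrow(s), object@u0, object@stride, sum(s$valid)))
})

setMethod("show", "BinaryIndicator", function(object) {
  cat(sprintf("BinaryIndicator '%s': %d/%d positive retained samples\n",
              object@featureName, sum(object@values), sum(object@mask)))
})
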