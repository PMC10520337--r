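#' @describeIn sizeDurationScaling core method on duration/size vectors.
#' @param sizes avalanche sizes matching the durations in \code{x}
#' @param tMin,tMax duration range analyzed
#' @param nBins number of log-spaced duration bins
#' @param splitT regime split duration; \code{NULL} fits a single regime over
#'   the whole range
#' @export
setMethod("sizeDurationScaling", "numeric",
          function(x, sizes, tMin, tMax, nBins = 16L, splitT = NULL, ...) {
  durations <- x
  if (length(durations) != length(sizes))
    stop("durations and sizes must have equal length")
  keep <- durations >= tMin & durations <= tMax & sizes > 0
  durations <- durations[keep]; sizes <- sizes[keep]
  if (length(durations) == 0) stop("no avalanches in the duration range")
  breaks <- exp(seq(log(tMin), log(tMax), length.out = nBins + 1))
  bin <- findInterval(durations, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  meanT <- tapply(durations, bin, mean)
  meanS <- tapply(sizes, bin, mean)
  curve <- data.frame(T_bin = as.numeric(meanT), mean_size = as.numeric(meanS))
  curve <- curve[order(curve$T_bin), , drop = FALSE]
  slope <- function(sub) {
    if (nrow(sub) < 3) return(NA_real_)
    unname(coef(lm(log(mean_size) ~ log(T_bin), data = sub))[2])
  }
  if (is.null(splitT)) {
    kLow <- slope(curve)
    kHigh <- NA_real_
    crossover <- tMax
  } else {
    kLow <- slope(curve[curve$T_bin < splitT, , drop = FALSE])
    kHigh <- slope(curve[curve$T_bin >= splitT, , drop = FALSE])
    crossover <- splitT
  }
  new("ScalingFit", kLow = kLow, kHigh = kHigh, crossoverT = crossover,
      binnedCurve = curve)
})

#' @describeIn sizeDurationScaling durations in seconds from a detection
#'   catalog; defaults follow the headline analysis (low regime
#'   0.01 < T < 0.4 s, high regime 0.4 < T <= 5 s).
#' @export
setMethod("sizeDurationScaling", "AvalancheCatalog",
          function(x, tMin = 0.01, tMax = 5, nBins = 16L, splitT = 0.4, ...) {
  sizeDurationScaling(avalancheDurations(x), sizes = avalancheSizes(x),
                      tMin = tMin, tMax = tMax, nBins = nBins,
                      splitT = splitT)
})

#' @describeIn sizeDurationScaling durations in generations from a branching
#'   simulation, single regime by default. The default range starts at 15
#'   generations because the critical Galton-Watson mean size has strong
#'   finite-duration corrections below that scale (the local slope only
#'   approaches its asymptote for durations of a few tens of generations).
#' @export
setMethod("sizeDurationScaling", "AvalancheSample",
          function(x, tMin = 15, tMax = 150, nBins = 12L, splitT = NULL, ...) {
  sizeDurationScaling(avalancheDurations(x), sizes = avalancheSizes(x),
                      tMin = tMin, tMax = tMax, nBins = nBins,
                      splitT = splitT)
})

#' Check the crackling-noise scaling relation
#'
#' At criticality the size, duration and size-versus-duration exponents are
#' tied by k = (alpha - 1) / (tau - 1). Given estimates and their
#' uncertainties, the predicted k and its first-order (delta-method)
#' propagated uncertainty are computed and compared with the measured k.
#'
#' @param tau size-distribution exponent (> 1)
#' @param alpha duration-distribution exponent
#' @param k measured size-versus-duration exponent
#' @param tauErr,alphaErr,kErr one-sigma uncertainties (default 0)
#' @return a list with \code{predictedK}, \code{predictedKErr},
#'   \code{combinedErr}, \code{discrepancy} (k - predictedK) and
#'   \code{consistent} (|discrepancy| < combined uncertainty)
#' @export
checkScalingRelation <- function(tau, alpha, k, tauErr = 0, alphaErr = 0,
                                 kErr = 0) {
  if (tau <= 1) stop("tau must exceed 1 (the relation diverges at tau = 1)")
  predictedK <- (alpha - 1) / (tau - 1)
  predictedKErr <- sqrt((alphaErr / (tau - 1))^2 +
                          ((alpha - 1) * tauErr / (tau - 1)^2)^2)
  combinedErr <- sqrt(predictedKErr^2 + kErr^2)
  discrepancy <- k - predictedK
  list(predictedK = predictedK, predictedKErr = predictedKErr,
       combinedErr = combinedErr, discrepancy = discrepancy,
       consistent = abs(discrepancy) < combinedErr)
}

#' Threshold robustness sweep
#'
#' Reruns excursion detection, avalanche extraction, power-law fits, the
#' scaling fit and the branching estimate for a grid of thresholds, to check
#' that avalanche statistics are stable over a range of theta values.
#'
#' @param rec a z-scored \linkS4class{MultichannelRecording}
#' @param thetaList thresholds (SD units) to scan
#' @param sizeXmin,sizeXmax size fit range
#' @param durXmin,durXmax duration fit range (s)
#' @param scalingTMin,scalingTMax,scalingSplitT scaling-fit range and split
#' @param sizeMode size definition passed to \code{\link{extractAvalanches}}
#' @return data.frame with one row per theta: tau, alpha, k, sigma,
#'   nAvalanches and totalAvalancheTime; failed fits are NA
#' @export
thresholdRobustnessSweep <- function(rec, thetaList = c(1, 1.5, 2, 2.5, 3),
                                     sizeXmin = 1, sizeXmax = 800,
                                     durXmin = 0.03, durXmax = 1,
                                     scalingTMin = 0.01, scalingTMax = 5,
                                     scalingSplitT = 0.4,
                                     sizeMode = "integrated") {
  stopifnot(is(rec, "MultichannelRecording"))
  if (any(thetaList <= 0)) stop("theta values must be positive")
  rows <- lapply(thetaList, function(theta) {
    raster <- detectExcursions(rec, theta)
    cat <- extractAvalanches(raster, rec, sizeMode = sizeMode)
    tryFit <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    tau <- tryFit(fitPowerLawMLE(avalancheSizes(cat), sizeXmin,
                                 sizeXmax)@exponent)
    alpha <- tryFit(fitPowerLawMLE(avalancheDurations(cat), durXmin,
                                   durXmax)@exponent)
    k <- tryFit(sizeDurationScaling(cat, tMin = scalingTMin,
                                    tMax = scalingTMax,
                                    splitT = scalingSplitT)@kLow)
    sigma <- tryFit(estimateBranchingParameter(cat, raster)$sigmaHat)
    data.frame(theta = theta, tau = tau, alpha = alpha, k = k, sigma = sigma,
               nAvalanches = nAvalanches(cat),
               totalAvalancheTime = sum(avalancheDurations(cat)))
  })
  do.call(rbind, rows)
}
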