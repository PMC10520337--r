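#' Sliding-window avalanche density
#'
#' For sliding windows of length \code{u0} seconds, computes
#' F_av(t) = (time occupied by avalanches in the window) / u0, together with
#' N_av (number of avalanches whose onset lies in the window) and the mean
#' duration of those avalanches. The window center t is reported. Windows
#' intersecting masked time are marked invalid.
#'
#' @param catalog an \linkS4class{AvalancheCatalog}
#' @param rec the \linkS4class{MultichannelRecording} the catalog came from
#' @param u0 window length in seconds (default 10, of the order of the
#'   longest avalanches)
#' @param stride window stride in seconds; default one sample (1/fs)
#' @return a \linkS4class{DensitySeries}
#' @export
avalancheDensity <- function(catalog, rec, u0 = 10,
                             stride = 1 / samplingRate(rec)) {
  stopifnot(is(catalog, "AvalancheCatalog"), is(rec, "MultichannelRecording"))
  fs <- samplingRate(rec)
  nSamp <- nSamples(rec)
  w <- as.integer(round(u0 * fs))
  if (w < 2) stop("u0 must cover at least 2 samples")
  if (w > nSamp) stop("u0 exceeds the recording length")
  strideSamp <- max(1L, as.integer(round(stride * fs)))

  av <- avalanches(catalog)
  occ <- logical(nSamp)
  onsetCount <- numeric(nSamp)
  onsetDur <- numeric(nSamp)
  for (i in seq_len(nrow(av))) {
    occ[av$onset_sample[i]:(av$offset_sample[i] - 1L)] <- TRUE
    onsetCount[av$onset_sample[i]] <- onsetCount[av$onset_sample[i]] + 1
    onsetDur[av$onset_sample[i]] <- onsetDur[av$onset_sample[i]] +
      av$duration_s[i]
  }
  csOcc <- c(0, cumsum(occ))
  csBad <- c(0, cumsum(!retainedMask(rec)))
  csN <- c(0, cumsum(onsetCount))
  csD <- c(0, cumsum(onsetDur))

  starts <- seq.int(1L, nSamp - w + 1L, by = strideSamp)
  ends <- starts + w - 1L
  occIn <- csOcc[ends + 1L] - csOcc[starts]
  badIn <- csBad[ends + 1L] - csBad[starts]
  nIn <- csN[ends + 1L] - csN[starts]
  dIn <- csD[ends + 1L] - csD[starts]
  series <- data.frame(
    t = rec@t0 + (starts - 1L + w / 2) / fs,
    Fav = occIn / w,
    Nav = nIn,
    meanT = ifelse(nIn > 0, dIn / nIn, NA_real_),
    valid = badIn == 0)
  new("DensitySeries", series = series, u0 = w / fs, stride = strideSamp / fs)
}

#' Per-stage density summary and first-versus-last N3 comparison
#'
#' Averages F_av over valid windows whose center lies in each sleep stage,
#' and compares the window densities of the first and last maximal N3 runs
#' of the night with a two-sample t test.
#'
#' @param density a \linkS4class{DensitySeries}
#' @param hyp the matching \linkS4class{Hypnogram}
#' @return a list with \code{stageMeans} (named numeric, NA for stages
#'   without valid windows) and \code{firstLastN3} (list with means, t
#'   statistic and p value, or NULL if fewer than two N3 runs exist)
#' @export
stageDensitySummary <- function(density, hyp) {
  stopifnot(is(density, "DensitySeries"), is(hyp, "Hypnogram"))
  s <- density@series
  stage <- .stageAt(hyp, s$t)
  ok <- s$valid
  stageMeans <- vapply(.STAGES, function(st) {
    sel <- ok & stage == st
    if (!any(sel)) NA_real_ else mean(s$Fav[sel])
  }, numeric(1))

  runs <- .logicalRuns(hyp@epochStages == "N3")
  firstLast <- NULL
  if (nrow(runs) >= 1) {
    spanOf <- function(r) {
      c(hyp@startS + (r[1] - 1) * hyp@epochLength,
        hyp@startS + r[2] * hyp@epochLength)
    }
    first <- spanOf(runs[1, ]); last <- spanOf(runs[nrow(runs), ])
    dFirst <- s$Fav[ok & s$t >= first[1] & s$t < first[2]]
    dLast <- s$Fav[ok & s$t >= last[1] & s$t < last[2]]
    if (nrow(runs) >= 2 && length(dFirst) >= 2 && length(dLast) >= 2) {
      tt <- tryCatch(t.test(dFirst, dLast), error = function(e) NULL)
      firstLast <- list(firstMean = mean(dFirst), lastMean = mean(dLast),
                        t = if (is.null(tt)) NA_real_
                            else unname(tt$statistic),
                        p = if (is.null(tt)) NA_real_ else tt$p.value)
    }
  }
  list(stageMeans = stageMeans, firstLastN3 = firstLast)
}
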