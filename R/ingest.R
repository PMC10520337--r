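#' Read a multichannel recording
#'
#' Reads either a TSV matrix (samples x channels with a header row of channel
#' labels) or a 16-bit EDF/EDF+ file. TSV carries no sampling rate, so
#' \code{fs} is required for it; for EDF the rate comes from the header and
#' annotation channels are ignored.
#'
#' @param path file path
#' @param format "tsv" or "edf"
#' @param fs sampling rate in Hz (required for TSV, ignored for EDF)
#' @return a raw-unit \linkS4class{MultichannelRecording} with an all-true mask
#' @export
readRecording <- function(path, format = c("tsv", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    if (is.null(fs)) stop("fs must be supplied for TSV recordings")
    if (file.info(path)$size == 0) stop("empty recording file: ", path)
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    if (nrow(dt) == 0 || ncol(dt) == 0) stop("empty recording file: ", path)
    sig <- t(as.matrix(dt))
    new("MultichannelRecording", signal = unname(sig), fs = fs,
        channelLabels = colnames(dt), mask = rep(TRUE, ncol(sig)),
        t0 = 0, zscored = FALSE)
  } else {
    readEDF(path)
  }
}

#' Write a recording as a TSV matrix
#'
#' Samples x channels with a header row of channel labels; the inverse of
#' \code{\link{readRecording}} with \code{format = "tsv"}.
#'
#' @param rec a \linkS4class{MultichannelRecording}
#' @param path output path
#' @return invisibly, the path
#' @export
writeRecordingTSV <- function(rec, path) {
  stopifnot(is(rec, "MultichannelRecording"))
  dt <- data.table::as.data.table(t(signalMatrix(rec)))
  data.table::setnames(dt, channelLabels(rec))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

## ---- EDF (European Data Format), 16-bit, 1-s data records -----------------

.padField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a recording to EDF
#'
#' Minimal EDF writer: 16-bit samples, 1-second data records (so \code{fs}
#' must be a whole number), per-channel physical scaling covering the signal
#' range. The recording is padded with zeros to a whole number of records.
#'
#' @param rec a \linkS4class{MultichannelRecording} with integer fs
#' @param path output path
#' @return invisibly, the path
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "MultichannelRecording"))
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export uses 1-s records and requires an integer sampling rate")
  fs <- as.integer(round(fs))
  sig <- signalMatrix(rec)
  ns <- nrow(sig)
  nRec <- as.integer(ceiling(ncol(sig) / fs))
  if (nRec * fs > ncol(sig))
    sig <- cbind(sig, matrix(0, ns, nRec * fs - ncol(sig)))
  physMax <- apply(abs(sig), 1, max)
  physMax[physMax == 0] <- 1
  digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .padField("0", 8), .padField("X X X X", 80), .padField("Startdate X", 80),
    .padField("01.01.00", 8), .padField("00.00.00", 8),
    .padField(256 + 256 * ns, 8), .padField("", 44),
    .padField(nRec, 8), .padField(1, 8), .padField(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(channelLabels(rec), .padField, character(1), width = 16),
    rep(.padField("", 80), ns), rep(.padField("uV", 8), ns),
    vapply(-physMax, .padField, character(1), width = 8),
    vapply(physMax, .padField, character(1), width = 8),
    rep(.padField(-digMax, 8), ns), rep(.padField(digMax, 8), ns),
    rep(.padField("", 80), ns), rep(.padField(fs, 8), ns),
    rep(.padField("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  scale <- digMax / physMax
  for (r in seq_len(nRec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- round(sig[, cols, drop = FALSE] * scale)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording
#'
#' Reads 16-bit EDF with equal sampling rate across signal channels;
#' EDF+ annotation channels ("EDF Annotations") are skipped.
#'
#' @param path EDF file path
#' @return a raw-unit \linkS4class{MultichannelRecording}
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.info(path)$size < 256) stop("not a valid EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 184, useBytes = TRUE)
  headerBytes <- as.integer(readChar(con, 8, useBytes = TRUE))
  readChar(con, 44, useBytes = TRUE)
  nRec <- as.integer(readChar(con, 8, useBytes = TRUE))
  recDur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))
  if (is.na(ns) || ns < 1) stop("not a valid EDF file: ", path)
  rd <- function(w) vapply(seq_len(ns), function(i)
    trimws(readChar(con, w, useBytes = TRUE)), character(1))
  labels <- rd(16); rd(80); rd(8)
  physMin <- as.numeric(rd(8)); physMax <- as.numeric(rd(8))
  digMin <- as.numeric(rd(8)); digMax <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8))
  rd(32)
  seek(con, headerBytes)
  keep <- labels != "EDF Annotations"
  sig <- matrix(0, sum(keep), nRec * max(spr[keep]))
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      if (keep[i]) {
        k <- sum(keep[seq_len(i)])
        cols <- ((r - 1) * spr[i] + 1):(r * spr[i])
        sig[k, cols] <- physMin[i] + scale[i] * (raw - digMin[i])
      }
    }
  }
  fs <- spr[keep][1] / recDur
  if (length(unique(spr[keep])) > 1)
    stop("channels with mixed sampling rates are not supported")
  new("MultichannelRecording", signal = sig, fs = fs,
      channelLabels = labels[keep], mask = rep(TRUE, ncol(sig)),
      t0 = 0, zscored = FALSE)
}

#' Mask artifact or wake intervals
#'
#' Marks the listed half-open time intervals [start_s, end_s) as not retained.
#' The time axis is preserved (samples are masked in place, not deleted) so
#' hypnogram and CAP alignment stays exact; masked samples are excluded from
#' all downstream statistics.
#'
#' @param rec a \linkS4class{MultichannelRecording}
#' @param intervals 2-column matrix or data.frame of (start_s, end_s)
#' @return the recording with an updated mask
#' @export
applyArtifactMask <- function(rec, intervals) {
  stopifnot(is(rec, "MultichannelRecording"))
  intervals <- .checkIntervals(intervals)
  if (nrow(intervals) == 0) return(rec)
  span <- nSamples(rec) / samplingRate(rec)
  if (any(intervals[, 1] < rec@t0 - 1e-9) ||
      any(intervals[, 2] > rec@t0 + span + 1e-9))
    stop("mask intervals must lie within the recording span")
  bad <- .intervalsToSamples(intervals - rec@t0, samplingRate(rec),
                             nSamples(rec))
  rec@mask <- rec@mask & !bad
  validObject(rec)
  rec
}

#' Z-score normalize a recording per channel
#'
#' Standardizes every channel to zero mean and unit SD using moments computed
#' over retained samples only (a single global pass, not sliding-window).
#' Idempotent up to numerical tolerance.
#'
#' @param rec a \linkS4class{MultichannelRecording}
#' @return the normalized recording with \code{isZScored(x)} TRUE
#' @export
zscoreNormalize <- function(rec) {
  stopifnot(is(rec, "MultichannelRecording"))
  if (!any(rec@mask)) stop("no retained samples to normalize over")
  kept <- rec@signal[, rec@mask, drop = FALSE]
  mu <- rowMeans(kept)
  sdv <- sqrt(rowSums((kept - mu)^2) / (ncol(kept) - 1))
  if (any(sdv <= 0 | !is.finite(sdv))) {
    bad <- channelLabels(rec)[sdv <= 0 | !is.finite(sdv)]
    stop("zero-variance channel(s): ", paste(bad, collapse = ", "))
  }
  rec@signal <- (rec@signal - mu) / sdv
  rec@zscored <- TRUE
  validObject(rec)
  rec
}

#' Detect supra-threshold excursions
#'
#' Marks samples where |z| strictly exceeds \code{theta} SD on a retained
#' sample. A sample at exactly theta is not an excursion.
#'
#' @param rec a z-scored \linkS4class{MultichannelRecording}
#' @param theta threshold in SD units (default 2)
#' @return an \linkS4class{ExcursionRaster}
#' @export
detectExcursions <- function(rec, theta = 2) {
  stopifnot(is(rec, "MultichannelRecording"))
  if (theta <= 0) stop("theta must be > 0")
  if (!isZScored(rec))
    stop("recording must be z-scored before excursion detection")
  beyond <- abs(rec@signal) > theta
  beyond[, !rec@mask] <- FALSE
  new("ExcursionRaster", beyond = beyond, theta = theta,
      fs = samplingRate(rec), mask = rec@mask)
}

#' Amplitude-distribution Gaussianity report
#'
#' Pools z-scored amplitudes over channels and retained samples, bins them,
#' fits a Gaussian density by least squares, and reports the smallest |z| at
#' which the empirical density persistently exceeds the fit by more than
#' \code{tolerance} (relative excess). This is the check that motivates a
#' 2-SD avalanche threshold: amplitude distributions of correlated,
#' burst-laden signals depart from the Gaussian fit around that scale.
#'
#' @param rec a z-scored \linkS4class{MultichannelRecording} with at least
#'   1e4 retained samples
#' @param tolerance relative excess threshold (Inf disables detection; the
#'   onset is then reported as Inf)
#' @param binWidth histogram bin width in SD units
#' @param persistBins number of consecutive bins that must exceed tolerance
#' @param minExpected bins with fewer expected counts under the fit are
#'   excluded (tail noise)
#' @return a list with \code{amplitudeHistogram} (data.frame z, density),
#'   \code{gaussianFit} (mean, sd), and \code{deviationOnsetSD}
#' @export
gaussianityReport <- function(rec, tolerance = 0.2, binWidth = 0.1,
                              persistBins = 3L, minExpected = 20) {
  stopifnot(is(rec, "MultichannelRecording"))
  z <- as.numeric(rec@signal[, rec@mask, drop = FALSE])
  if (length(z) < 1e4)
    stop("need at least 1e4 retained samples for the Gaussianity report")
  lim <- max(4, min(8, max(abs(z))))
  breaks <- seq(-lim - binWidth, lim + binWidth, by = binWidth)
  z <- z[z > breaks[1] & z <= breaks[length(breaks)]]
  h <- hist(z, breaks = breaks, plot = FALSE)
  dens <- h$density
  mids <- h$mids
  ## least-squares Gaussian fit of the binned density
  fit <- optim(c(0, 1), function(p) {
    if (p[2] <= 0) return(Inf)
    sum((dens - dnorm(mids, p[1], p[2]))^2)
  }, method = "Nelder-Mead")
  mu <- fit$par[1]; sdv <- fit$par[2]
  expected <- dnorm(mids, mu, sdv) * length(z) * binWidth
  onset <- Inf
  if (is.finite(tolerance)) {
    absZ <- abs(mids - mu)
    ord <- order(absZ)
    usable <- expected[ord] >= minExpected
    excess <- (dens[ord] - dnorm(mids[ord], mu, sdv)) /
      pmax(dnorm(mids[ord], mu, sdv), .Machine$double.eps)
    flag <- excess > tolerance & usable
    ## smallest |z| from which the excess persists for persistBins usable bins
    idx <- which(flag)
    for (i in idx) {
      nxt <- which(usable & absZ[ord] >= absZ[ord][i])
      nxt <- nxt[order(absZ[ord][nxt])][seq_len(min(persistBins, length(nxt)))]
      if (length(nxt) >= persistBins && all(flag[nxt])) {
        onset <- absZ[ord][i]
        break
      }
    }
  }
  list(amplitudeHistogram = data.frame(z = mids, density = dens),
       gaussianFit = c(mean = mu, sd = sdv),
       deviationOnsetSD = onset)
}
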