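## Shared fixture builders. Everything is generated in code, seeded.

## Recording from a raw signal matrix (channels x samples), all retained.
mkRecording <- function(signal, fs = 100) {
  new("MultichannelRecording", signal = signal, fs = fs,
      channelLabels = sprintf("ch%02d", seq_len(nrow(signal))),
      mask = rep(TRUE, ncol(signal)), t0 = 0, zscored = FALSE)
}

## Recording flagged as z-scored from a crafted signal whose rows are
## recentred to mean zero (for boundary-exact detection fixtures).
mkZRecording <- function(signal, fs = 100, mask = rep(TRUE, ncol(signal))) {
  signal <- signal - rowMeans(signal)
  new("MultichannelRecording", signal = signal, fs = fs,
      channelLabels = sprintf("ch%02d", seq_len(nrow(signal))),
      mask = mask, t0 = 0, zscored = TRUE)
}

## Random z-scored Gaussian recording.
randomZRec <- function(nCh = 3, nSamp = 2000, fs = 100, seed = 1) {
  set.seed(seed)
  zscoreNormalize(mkRecording(matrix(rnorm(nCh * nSamp), nCh), fs))
}

## Brute-force avalanche extraction: per-sample scan over the raster,
## independent of the package's run-length implementation.
bruteForceAvalanches <- function(raster, rec, sizeMode = "integrated") {
  beyond <- raster@beyond
  nSamp <- ncol(beyond)
  active <- vapply(seq_len(nSamp), function(t) any(beyond[, t]), logical(1))
  out <- NULL
  t <- 1L
  while (t <= nSamp) {
    if (active[t]) {
      start <- t
      while (t <= nSamp && active[t]) t <- t + 1L
      end <- t - 1L
      boundedLeft <- start > 1L && raster@mask[start - 1L]
      boundedRight <- end < nSamp && raster@mask[end + 1L]
      if (boundedLeft && boundedRight) {
        size <- 0
        nch <- 0L
        for (ch in seq_len(nrow(beyond))) {
          sel <- start:end
          hit <- beyond[ch, sel]
          if (any(hit)) nch <- nch + 1L
          size <- size + sum(abs(rec@signal[ch, sel][hit]))
        }
        if (sizeMode == "integrated") size <- size / raster@fs
        out <- rbind(out, c(start, end, size, nch))
      }
    } else t <- t + 1L
  }
  if (is.null(out))
    out <- matrix(numeric(0), ncol = 4)
  colnames(out) <- c("start", "end", "size", "n_channels")
  out
}

## Truncate a surrogate night (recording + hypnogram + CAP + ground truth)
## to its first nEpochs epochs, keeping all objects aligned.
truncateNight <- function(sur, nEpochs) {
  fs <- samplingRate(sur$rec)
  nSamp <- as.integer(nEpochs * 30 * fs)
  hyp <- new("Hypnogram", epochStages = epochStages(sur$hyp)[1:nEpochs],
             epochLength = 30, startS = 0)
  ph <- capPhases(sur$cap)
  ph <- ph[ph$onset_s + ph$duration_s <= nEpochs * 30, , drop = FALSE]
  cap <- new("CapAnnotation", phases = ph)
  rec <- new("MultichannelRecording",
             signal = sur$rec@signal[, 1:nSamp, drop = FALSE], fs = fs,
             channelLabels = channelLabels(sur$rec), mask = rep(TRUE, nSamp),
             t0 = 0, zscored = FALSE)
  gt <- sur$groundTruth[sur$groundTruth$offset_s <= nEpochs * 30, ,
                        drop = FALSE]
  list(rec = rec, hyp = hyp, cap = cap, groundTruth = gt)
}

## A small coupled surrogate night, cached per session (built once).
.surrogateCache <- new.env(parent = emptyenv())
smallSurrogate <- function() {
  if (!is.null(.surrogateCache$value)) return(.surrogateCache$value)
  arch <- architectureConfig(nCycles = 2L)
  hyp <- simulateHypnogram(arch, seed = 7)
  cap <- simulateCapAnnotations(hyp, arch, seed = 8)
  sur <- synthesizeRecording(hyp, cap, couplingConfig(), nChannels = 8L,
                             fs = 128, seed = 9)
  rec <- zscoreNormalize(sur$recording)
  raster <- detectExcursions(rec, 2)
  catalog <- extractAvalanches(raster, rec)
  .surrogateCache$value <- list(arch = arch, hyp = hyp, cap = cap,
                                groundTruth = sur$groundTruth, rec = rec,
                                raster = raster, catalog = catalog)
  .surrogateCache$value
}

## Brute-force window summation, independent of the cumulative-sum path.
bruteForceDensity <- function(catalog, rec, u0, stride) {
  fs <- samplingRate(rec)
  nSamp <- nSamples(rec)
  w <- as.integer(round(u0 * fs))
  strideSamp <- max(1L, as.integer(round(stride * fs)))
  av <- avalanches(catalog)
  occ <- logical(nSamp)
  for (i in seq_len(nrow(av)))
    occ[av$onset_sample[i]:(av$offset_sample[i] - 1L)] <- TRUE
  starts <- seq.int(1L, nSamp - w + 1L, by = strideSamp)
  t(vapply(starts, function(s0) {
    win <- s0:(s0 + w - 1L)
    onsetsIn <- which(av$onset_sample >= s0 & av$onset_sample <= s0 + w - 1L)
    c(Fav = sum(occ[win]) / w,
      Nav = length(onsetsIn),
      meanT = if (length(onsetsIn)) mean(av$duration_s[onsetsIn]) else NA_real_,
      valid = as.numeric(all(retainedMask(rec)[win])))
  }, numeric(4)))
}

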