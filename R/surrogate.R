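#' Coupling configuration for surrogate recordings
#'
#' Parameters controlling how burst (avalanche) injections into a surrogate
#' recording are modulated by sleep stage and CAP phase. The defaults encode
#' the coupling the analysis is meant to recover: injection rate highest in
#' slow-wave sleep (N3) and during CAP A phases (A1 strongest), suppressed in
#' phase B and NCAP; burst amplitude well above the 2-SD detection threshold
#' so injected intervals are recoverable even after z-scoring inflates the
#' per-channel SD.
#'
#' @param baseRate avalanche injections per second before modulation
#' @param stageMultipliers named factors for W, N1, N2, N3, REM
#' @param phaseMultipliers named factors for A1, A2, A3, B, NCAP (applied on
#'   top of the stage factor during NREM; outside NREM the factor is 1)
#' @param burstAmplitude peak burst amplitude in background-SD units
#' @param burstChannelFraction fraction of channels carrying each burst
#' @param burstDurationRange duration bounds (s) of the power-law burst
#'   duration distribution
#' @param burstDurationExponent exponent of that distribution
#' @param envelopeFloor the burst envelope is
#'   amplitude * (floor + (1 - floor) * sin(pi * u)), so the burst never drops
#'   below floor * amplitude inside its interval
#' @param minGap minimum gap (s) enforced between injected bursts
#' @return a validated list of class "CouplingConfig"
#' @export
couplingConfig <- function(
    baseRate = 0.3,
    stageMultipliers = c(W = 0.1, N1 = 0.5, N2 = 1.0, N3 = 2.0, REM = 0.3),
    phaseMultipliers = c(A1 = 3.0, A2 = 2.0, A3 = 1.5, B = 0.25, NCAP = 0.35),
    burstAmplitude = 8,
    burstChannelFraction = 0.25,
    burstDurationRange = c(0.2, 3),
    burstDurationExponent = 2,
    envelopeFloor = 0.6,
    minGap = 0.25) {
  if (baseRate < 0) stop("baseRate must be >= 0")
  if (any(stageMultipliers < 0) || any(phaseMultipliers < 0))
    stop("all multipliers must be >= 0")
  if (burstAmplitude <= 2)
    stop("burstAmplitude must exceed the 2-SD detection threshold")
  if (burstChannelFraction <= 0 || burstChannelFraction > 1)
    stop("burstChannelFraction must lie in (0, 1]")
  if (envelopeFloor < 0 || envelopeFloor >= 1)
    stop("envelopeFloor must lie in [0, 1)")
  structure(list(baseRate = baseRate, stageMultipliers = stageMultipliers,
                 phaseMultipliers = phaseMultipliers,
                 burstAmplitude = burstAmplitude,
                 burstChannelFraction = burstChannelFraction,
                 burstDurationRange = burstDurationRange,
                 burstDurationExponent = burstDurationExponent,
                 envelopeFloor = envelopeFloor, minGap = minGap),
            class = "CouplingConfig")
}

## Per-sample CAP phase labels ("A1","A2","A3","B","NCAP", or "" outside NREM)
.phasePerSample <- function(hyp, cap, fs, nSamp) {
  stageIdx <- .stageAt(hyp, (seq_len(nSamp) - 1) / fs)
  phase <- ifelse(stageIdx %in% c("N1", "N2", "N3"), "NCAP", "")
  ph <- capPhases(cap)
  for (i in seq_len(nrow(ph))) {
    from <- floor(ph$onset_s[i] * fs) + 1L
    to <- min(nSamp, ceiling((ph$onset_s[i] + ph$duration_s[i]) * fs))
    if (from <= to) phase[from:to] <- ph$label[i]
  }
  phase
}

#' Synthesize a surrogate multichannel recording
#'
#' Builds a recording of i.i.d. standard-Gaussian background with injected
#' high-amplitude bursts whose Poisson occurrence rate is modulated by the
#' current sleep stage and CAP phase. Each burst spans a random channel
#' subset with a half-sine envelope raised to a positive floor (so the whole
#' injected interval stays above threshold) and a random sign per channel;
#' burst durations are heavy-tailed. The exact injected intervals are
#' returned as ground truth.
#'
#' @param hyp a \linkS4class{Hypnogram} defining the time span and stages
#' @param cap a \linkS4class{CapAnnotation} (may be empty)
#' @param coupling a \code{\link{couplingConfig}}
#' @param nChannels number of channels
#' @param fs sampling rate in Hz
#' @param seed integer seed
#' @return a list with elements \code{recording}
#'   (\linkS4class{MultichannelRecording}, raw units) and \code{groundTruth}
#'   (data.frame with onset_s, offset_s of injected bursts)
#' @export
synthesizeRecording <- function(hyp, cap = NULL,
                                coupling = couplingConfig(),
                                nChannels = 19L, fs = 256, seed = NULL) {
  stopifnot(is(hyp, "Hypnogram"), inherits(coupling, "CouplingConfig"))
  if (nChannels < 1) stop("nChannels must be >= 1")
  if (fs <= 0) stop("fs must be positive")
  if (is.null(cap)) cap <- new("CapAnnotation",
                               phases = data.frame(onset_s = numeric(0),
                                                   duration_s = numeric(0),
                                                   label = character(0)))
  if (!is.null(seed)) set.seed(seed)
  nSamp <- as.integer(round(totalDuration(hyp) * fs))
  signal <- matrix(rnorm(nChannels * nSamp), nrow = nChannels)

  truth <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  if (coupling$baseRate > 0) {
    ## per-second piecewise-constant rate from stage and phase multipliers
    secs <- seq_len(floor(nSamp / fs))
    tSec <- secs - 0.5
    stage <- .stageAt(hyp, tSec)
    phase <- .phasePerSample(hyp, cap, 1, length(secs))
    mult <- coupling$stageMultipliers[stage]
    phaseFac <- ifelse(phase == "", 1, coupling$phaseMultipliers[phase])
    lambda <- coupling$baseRate * as.numeric(mult) * as.numeric(phaseFac)
    nInj <- rpois(1, sum(lambda))
    if (nInj > 0) {
      secIdx <- sample.int(length(secs), nInj, replace = TRUE,
                           prob = lambda / sum(lambda))
      onsets <- sort((secIdx - 1) + runif(nInj))
      durs <- samplePowerLaw(coupling$burstDurationExponent,
                             coupling$burstDurationRange[1],
                             coupling$burstDurationRange[2], nInj)
      ## enforce non-overlap with a minimum gap; overlapping candidates drop
      keep <- logical(nInj)
      lastEnd <- -Inf
      for (i in seq_len(nInj)) {
        if (onsets[i] >= lastEnd + coupling$minGap &&
            onsets[i] + durs[i] <= nSamp / fs) {
          keep[i] <- TRUE
          lastEnd <- onsets[i] + durs[i]
        }
      }
      onsets <- onsets[keep]; durs <- durs[keep]
      nCh <- max(1L, as.integer(ceiling(coupling$burstChannelFraction *
                                          nChannels)))
      for (i in seq_along(onsets)) {
        i0 <- floor(onsets[i] * fs) + 1L
        i1 <- min(nSamp, ceiling((onsets[i] + durs[i]) * fs))
        len <- i1 - i0 + 1L
        if (len < 1) next
        env <- coupling$burstAmplitude *
          (coupling$envelopeFloor + (1 - coupling$envelopeFloor) *
             sin(pi * (seq_len(len) - 0.5) / len))
        chans <- sample.int(nChannels, nCh)
        signs <- sample(c(-1, 1), nCh, replace = TRUE)
        signal[chans, i0:i1] <- signal[chans, i0:i1] +
          outer(signs, env)
        truth <- rbind(truth,
                       data.frame(onset_s = (i0 - 1) / fs, offset_s = i1 / fs))
      }
    }
  }
  rec <- new("MultichannelRecording", signal = signal, fs = fs,
             channelLabels = sprintf("ch%02d", seq_len(nChannels)),
             mask = rep(TRUE, nSamp), t0 = 0, zscored = FALSE)
  list(recording = rec, groundTruth = truth)
}

#' Recovery quality of injected intervals
#'
#' For every ground-truth interval, the Jaccard index between the interval
#' and the union of detected avalanches overlapping it is computed; the mean
#' over ground-truth intervals quantifies how well detection recovers the
#' injections.
#'
#' @param groundTruth data.frame with onset_s, offset_s (as returned by
#'   \code{\link{synthesizeRecording}})
#' @param catalog an \linkS4class{AvalancheCatalog}
#' @return a list with \code{meanJaccard}, \code{perInterval} (numeric
#'   vector) and \code{nMatched} (intervals with at least one overlapping
#'   detection)
#' @export
recoveryJaccard <- function(groundTruth, catalog) {
  stopifnot(is(catalog, "AvalancheCatalog"))
  av <- avalanches(catalog)
  det <- cbind(av$onset_s, av$offset_s)
  per <- vapply(seq_len(nrow(groundTruth)), function(i) {
    tr <- c(groundTruth$onset_s[i], groundTruth$offset_s[i])
    if (nrow(av) == 0) return(0)
    ov <- .overlapLengths(tr, det)
    hit <- ov > 0
    if (!any(hit)) return(0)
    inter <- sum(ov[hit])
    union <- (tr[2] - tr[1]) + sum(det[hit, 2] - det[hit, 1]) - inter
    inter / union
  }, numeric(1))
  list(meanJaccard = mean(per), perInterval = per, nMatched = sum(per > 0))
}
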