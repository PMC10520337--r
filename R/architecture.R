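#' Sleep-architecture generator configuration
#'
#' Bundles the parameters of the hypnogram and CAP generators. Defaults
#' reproduce the macro- and micro-architecture of a healthy adult cohort:
#' stage fractions of total sleep time N1 7.23%, N2 48.47%, N3 23.99%,
#' REM 20.30%; CAP rates per NREM stage N1 41.69%, N2 48.36%, N3 53.37%;
#' phase A mean length 8.59 s and phase B 20.67 s (both clipped to the
#' scoring bounds [2, 60] s); about 9.6 CAP cycles per sequence; A1 subtypes
#' dominating N3 and A3 dominating N1.
#'
#' @param nCycles number of NREM-REM cycles per night
#' @param epochLength epoch length in seconds (fixed at 30)
#' @param stageFractions named fractions of sleep time per stage, summing to 1
#' @param stageDwellMeans named mean dwell per stage visit in seconds; the
#'   per-cycle visit pattern is N1, N2, N3, N2, REM (stages with zero target
#'   fraction are skipped), so N2 dwell applies to each of its two visits
#' @param capRateByStage target CAP rate (CAP time / NREM time) per NREM stage
#' @param phaseDurationParams list with elements \code{A} and \code{B}, each
#'   \code{c(mean, sdlog)} of a lognormal phase-duration law (seconds),
#'   clipped to [2, 60] s
#' @param subtypeMixByStage named list mapping N1/N2/N3 to probabilities
#'   \code{c(A1, A2, A3)} summing to 1
#' @param meanCyclesPerSequence mean number of A-B cycles per CAP sequence
#'   (minimum 2)
#' @param minInterSequenceGap minimum NCAP gap between CAP sequences in
#'   seconds (> 60 s so distinct sequences never merge under the 60-s rule)
#' @return a validated list of class "ArchitectureConfig"
#' @export
architectureConfig <- function(
    nCycles = 5L,
    epochLength = 30,
    stageFractions = c(N1 = 0.0723, N2 = 0.4847, N3 = 0.2399, REM = 0.2030),
    stageDwellMeans = NULL,
    capRateByStage = c(N1 = 0.4169, N2 = 0.4836, N3 = 0.5337),
    phaseDurationParams = list(A = c(mean = 8.59, sdlog = 0.40),
                               B = c(mean = 20.67, sdlog = 0.50)),
    subtypeMixByStage = list(N1 = c(A1 = 0.05, A2 = 0.35, A3 = 0.60),
                             N2 = c(A1 = 0.25, A2 = 0.35, A3 = 0.40),
                             N3 = c(A1 = 0.80, A2 = 0.12, A3 = 0.08)),
    meanCyclesPerSequence = 9.6,
    minInterSequenceGap = 61) {
  if (epochLength != 30) stop("epochLength is fixed at 30 s")
  ## cohort tables print rounded percentages; renormalize near-1 totals so
  ## the stored fractions sum to 1 exactly
  if (abs(sum(stageFractions) - 1) > 1e-3)
    stop("stageFractions must sum to 1")
  stageFractions <- stageFractions / sum(stageFractions)
  if (any(stageFractions < 0)) stop("stageFractions must be non-negative")
  bad <- setdiff(names(stageFractions), .STAGES)
  if (length(bad)) stop("unknown stages in stageFractions: ",
                        paste(bad, collapse = ", "))
  if (is.null(stageDwellMeans)) {
    ## Derive dwell means from the target fractions over a 90-min cycle,
    ## splitting N2 over its two visits per cycle.
    cycleLen <- 90 * 60
    stageDwellMeans <- vapply(names(stageFractions), function(s) {
      visits <- if (s == "N2") 2 else 1
      stageFractions[[s]] * cycleLen / visits
    }, numeric(1))
    names(stageDwellMeans) <- names(stageFractions)
  }
  if (any(capRateByStage < 0 | capRateByStage > 1))
    stop("capRateByStage must lie in [0, 1]")
  for (s in names(subtypeMixByStage)) {
    m <- subtypeMixByStage[[s]]
    if (abs(sum(m) - 1) > 1e-9) stop("subtype mix for ", s, " must sum to 1")
  }
  if (meanCyclesPerSequence < 2)
    stop("meanCyclesPerSequence must be >= 2")
  if (minInterSequenceGap <= 60)
    stop("minInterSequenceGap must exceed 60 s (the NCAP scoring rule)")
  structure(list(nCycles = as.integer(nCycles), epochLength = epochLength,
                 stageFractions = stageFractions,
                 stageDwellMeans = stageDwellMeans,
                 capRateByStage = capRateByStage,
                 phaseDurationParams = phaseDurationParams,
                 subtypeMixByStage = subtypeMixByStage,
                 meanCyclesPerSequence = meanCyclesPerSequence,
                 minInterSequenceGap = minInterSequenceGap),
            class = "ArchitectureConfig")
}

#' Simulate a cyclic hypnogram
#'
#' Semi-Markov generator of 30-s epoch stage labels. Each NREM-REM cycle
#' follows the descending-then-ascending visit pattern N1, N2, N3, N2, REM
#' (deepening from light sleep to slow-wave sleep, then lightening into REM);
#' dwell times are exponential with the configured per-visit means, rounded
#' to epochs with a 1-epoch minimum. Stages with zero target fraction are
#' dropped from the pattern, so a config concentrating all mass on one stage
#' yields a constant hypnogram.
#'
#' @param config an \code{\link{architectureConfig}}
#' @param seed integer seed
#' @return a \linkS4class{Hypnogram}
#' @export
simulateHypnogram <- function(config = architectureConfig(), seed = NULL) {
  stopifnot(inherits(config, "ArchitectureConfig"))
  if (config$nCycles < 1) stop("nCycles must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pattern <- c("N1", "N2", "N3", "N2", "REM")
  present <- names(config$stageFractions)[config$stageFractions > 0]
  if (length(present) == 0) stop("no stage has positive target fraction")
  pattern <- pattern[pattern %in% present]
  ## stages outside the cyclic pattern (e.g. a wake-only config) fall back to
  ## a plain visit sequence
  if (length(pattern) == 0) pattern <- intersect(.STAGES, present)
  epochs <- character(0)
  for (cyc in seq_len(config$nCycles)) {
    for (s in pattern) {
      dwell <- rexp(1, 1 / config$stageDwellMeans[[s]])
      nEpochs <- max(1L, as.integer(round(dwell / config$epochLength)))
      epochs <- c(epochs, rep(s, nEpochs))
    }
  }
  new("Hypnogram", epochStages = epochs, epochLength = config$epochLength,
      startS = 0)
}

## Maximal runs of NREM epochs -> intervals in seconds with the per-epoch
## stage labels attached.
.nremRuns <- function(hyp) {
  stages <- hyp@epochStages
  isN <- stages %in% c("N1", "N2", "N3")
  runs <- .logicalRuns(isN)
  lapply(seq_len(nrow(runs)), function(i) {
    e0 <- runs[i, 1]; e1 <- runs[i, 2]
    list(start = hyp@startS + (e0 - 1) * hyp@epochLength,
         end = hyp@startS + e1 * hyp@epochLength,
         epochStages = stages[e0:e1])
  })
}

.stageAt <- function(hyp, t) {
  idx <- pmin(length(hyp@epochStages),
              pmax(1L, floor((t - hyp@startS) / hyp@epochLength) + 1L))
  hyp@epochStages[idx]
}

.rlnormMean <- function(n, mean, sdlog) {
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate CAP annotations for a hypnogram
#'
#' Places CAP sequences (alternating A and B phases) inside NREM sleep only.
#' Within each maximal NREM run, NCAP gaps (exponential, floored at the
#' configured minimum > 60 s) alternate with CAP sequences of 2 + Poisson
#' cycles; each cycle is an A phase followed by a B phase, with lognormal
#' durations clipped to [2, 60] s and the A subtype drawn from the mix of the
#' sleep stage at the phase onset. Gap lengths are calibrated so the expected
#' CAP rate matches \code{capRateByStage} for the stage at the sequence start.
#' Phases that would cross the end of the NREM run are dropped.
#'
#' @param hyp a \linkS4class{Hypnogram} containing NREM epochs
#' @param config an \code{\link{architectureConfig}}
#' @param seed integer seed
#' @return a \linkS4class{CapAnnotation}
#' @export
simulateCapAnnotations <- function(hyp, config = architectureConfig(),
                                   seed = NULL) {
  stopifnot(is(hyp, "Hypnogram"), inherits(config, "ArchitectureConfig"))
  runs <- .nremRuns(hyp)
  if (length(runs) == 0) stop("hypnogram contains no NREM epochs")
  if (any(config$capRateByStage < 0 | config$capRateByStage > 1))
    stop("capRateByStage must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  pA <- config$phaseDurationParams$A
  pB <- config$phaseDurationParams$B
  meanCycleLen <- pA[["mean"]] + pB[["mean"]]
  meanSeqLen <- config$meanCyclesPerSequence * meanCycleLen
  onset <- duration <- numeric(0)
  label <- character(0)
  for (run in runs) {
    t <- run$start
    while (t < run$end) {
      stage <- .stageAt(hyp, min(t, run$end - 1e-9))
      rate <- config$capRateByStage[[stage]]
      if (is.null(rate) || rate <= 0) { t <- t + config$epochLength; next }
      gapMean <- max(config$minInterSequenceGap,
                     meanSeqLen * (1 - rate) / rate)
      excess <- max(0, gapMean - config$minInterSequenceGap)
      gap <- config$minInterSequenceGap + rexp(1, 1 / max(excess, 1e-6))
      t <- t + gap
      if (t >= run$end) break
      nCyc <- 2L + rpois(1, config$meanCyclesPerSequence - 2)
      for (cyc in seq_len(nCyc)) {
        stageHere <- .stageAt(hyp, min(t, run$end - 1e-9))
        durA <- min(60, max(2, .rlnormMean(1, pA[["mean"]], pA[["sdlog"]])))
        if (t + durA > run$end) { t <- run$end; break }
        mix <- config$subtypeMixByStage[[stageHere]]
        if (is.null(mix)) mix <- c(A1 = 1/3, A2 = 1/3, A3 = 1/3)
        sub <- sample(names(mix), 1, prob = mix)
        onset <- c(onset, t); duration <- c(duration, durA)
        label <- c(label, sub)
        t <- t + durA
        durB <- min(60, max(2, .rlnormMean(1, pB[["mean"]], pB[["sdlog"]])))
        if (t + durB > run$end) { t <- run$end; break }
        onset <- c(onset, t); duration <- c(duration, durB)
        label <- c(label, "B")
        t <- t + durB
      }
    }
  }
  ph <- data.frame(onset_s = onset, duration_s = duration, label = label,
                   stringsAsFactors = FALSE)
  ph <- ph[order(ph$onset_s), , drop = FALSE]
  rownames(ph) <- NULL
  new("CapAnnotation", phases = ph)
}
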