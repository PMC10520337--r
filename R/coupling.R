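## CAP sequences: group phases separated by gaps <= maxGap, count A->B
## cycles per group, and return spans (start, end) of groups with at least
## minCycles cycles.
.capSequences <- function(cap, minCycles = 2L, maxGap = 60) {
  ph <- capPhases(cap)
  if (nrow(ph) == 0)
    return(list(spans = matrix(numeric(0), ncol = 2,
                               dimnames = list(NULL, c("start", "end"))),
                cycleCounts = integer(0), groups = list()))
  ends <- ph$onset_s + ph$duration_s
  gapBefore <- c(Inf, ph$onset_s[-1] - ends[-nrow(ph)])
  groupId <- cumsum(gapBefore > maxGap)
  spans <- list(); cycles <- integer(0); groups <- list()
  for (g in unique(groupId)) {
    idx <- which(groupId == g)
    lab <- ph$label[idx]
    isA <- lab %in% c("A1", "A2", "A3")
    nCyc <- sum(isA[-length(isA)] & lab[-1] == "B")
    if (length(isA) == 1) nCyc <- 0L
    if (nCyc >= minCycles) {
      spans[[length(spans) + 1]] <- c(ph$onset_s[idx[1]], ends[idx[length(idx)]])
      cycles <- c(cycles, nCyc)
      groups[[length(groups) + 1]] <- idx
    }
  }
  spans <- if (length(spans)) do.call(rbind, spans)
           else matrix(numeric(0), ncol = 2)
  colnames(spans) <- c("start", "end")
  list(spans = spans, cycleCounts = cycles, groups = groups)
}

#' Build per-sample binary indicators
#'
#' Constructs 0/1 indicator series on the recording's sample grid for
#' avalanche occurrence, the five sleep stages, and the CAP features
#' (CAP, NCAP, A, A1, A2, A3, B). Stage indicators are the 30-s epoch labels
#' upsampled to the sample grid; CAP is the union of qualifying CAP-sequence
#' spans (at least \code{minCycles} A-B cycles, inter-phase gaps at most
#' 60 s); NCAP is NREM sleep outside any CAP sequence. All indicators are
#' forced to 0 on masked samples.
#'
#' @param catalog an \linkS4class{AvalancheCatalog}
#' @param hyp a \linkS4class{Hypnogram}
#' @param cap a \linkS4class{CapAnnotation} (may be empty)
#' @param rec the \linkS4class{MultichannelRecording} defining the grid
#' @param minCycles minimum A-B cycles for a CAP sequence (default 2)
#' @return named list of \linkS4class{BinaryIndicator} objects with features
#'   avalanche, W, N1, N2, N3, REM, CAP, NCAP, A, A1, A2, A3, B
#' @export
buildIndicators <- function(catalog, hyp, cap = NULL, rec, minCycles = 2L) {
  stopifnot(is(catalog, "AvalancheCatalog"), is(hyp, "Hypnogram"),
            is(rec, "MultichannelRecording"))
  nSamp <- nSamples(rec)
  fs <- samplingRate(rec)
  if (nSamp / fs < totalDuration(hyp) - hyp@epochLength)
    stop("recording is shorter than the hypnogram")
  if (is.null(cap)) cap <- new("CapAnnotation",
                               phases = data.frame(onset_s = numeric(0),
                                                   duration_s = numeric(0),
                                                   label = character(0)))
  mask <- retainedMask(rec)
  mk <- function(values, name) {
    new("BinaryIndicator", values = values & mask, featureName = name,
        mask = mask)
  }
  out <- list()

  av <- avalanches(catalog)
  avVec <- logical(nSamp)
  for (i in seq_len(nrow(av)))
    avVec[av$onset_sample[i]:(av$offset_sample[i] - 1L)] <- TRUE
  out$avalanche <- mk(avVec, "avalanche")

  stagePerSample <- .stageAt(hyp, (seq_len(nSamp) - 1) / fs)
  for (s in .STAGES) out[[s]] <- mk(stagePerSample == s, s)
  nrem <- stagePerSample %in% c("N1", "N2", "N3")

  ph <- capPhases(cap)
  phaseVec <- function(labels) {
    v <- logical(nSamp)
    sel <- which(ph$label %in% labels)
    for (i in sel) {
      from <- floor(ph$onset_s[i] * fs) + 1L
      to <- min(nSamp, ceiling((ph$onset_s[i] + ph$duration_s[i]) * fs))
      if (from <= to) v[from:to] <- TRUE
    }
    v
  }
  seqs <- .capSequences(cap, minCycles = minCycles)
  capVec <- logical(nSamp)
  for (i in seq_len(nrow(seqs$spans))) {
    from <- floor(seqs$spans[i, 1] * fs) + 1L
    to <- min(nSamp, ceiling(seqs$spans[i, 2] * fs))
    if (from <= to) capVec[from:to] <- TRUE
  }
  out$CAP <- mk(capVec, "CAP")
  out$NCAP <- mk(nrem & !capVec, "NCAP")
  out$A <- mk(phaseVec(c("A1", "A2", "A3")), "A")
  out$A1 <- mk(phaseVec("A1"), "A1")
  out$A2 <- mk(phaseVec("A2"), "A2")
  out$A3 <- mk(phaseVec("A3"), "A3")
  out$B <- mk(phaseVec("B"), "B")
  out
}

#' Phi coefficient of two binary indicators
#'
#' Pearson correlation of two 0/1 series over the retained samples; for
#' binary variables this equals the 2x2 contingency-table phi coefficient.
#'
#' @param x,y \linkS4class{BinaryIndicator} objects on the same grid
#' @return phi in [-1, 1]
#' @export
phiCorrelation <- function(x, y) {
  stopifnot(is(x, "BinaryIndicator"), is(y, "BinaryIndicator"))
  if (!identical(x@mask, y@mask))
    stop("indicators must share the same retained-sample set")
  xv <- x@values[x@mask]
  yv <- y@values[y@mask]
  if (all(xv) || !any(xv) || all(yv) || !any(yv))
    stop("phi is undefined for a constant indicator")
  as.numeric(cor(xv, yv))
}

#' Occupancy fraction of one indicator within another
#'
#' Fraction of b's positive retained samples on which a is also positive,
#' e.g. the percentage of phase-A time occupied by avalanches.
#'
#' @param a,b \linkS4class{BinaryIndicator} objects on the same grid
#' @return fraction in [0, 1]
#' @export
occupancyFraction <- function(a, b) {
  stopifnot(is(a, "BinaryIndicator"), is(b, "BinaryIndicator"))
  if (!identical(a@mask, b@mask))
    stop("indicators must share the same retained-sample set")
  bPos <- b@values & b@mask
  if (!any(bPos)) stop("reference indicator has no positive samples")
  sum(a@values & bPos) / sum(bPos)
}

#' Correlation table of avalanche occurrence against architecture features
#'
#' Computes phi(avalanche, feature) for the standard CAP feature set, in the
#' column order NCAP, CAP, B, A3, A2, A1, A. Features with constant
#' indicators are reported as NA.
#'
#' @param indicators a list from \code{\link{buildIndicators}}
#' @param features feature names to correlate against "avalanche"
#' @return data.frame with columns feature and phi
#' @export
correlationTable <- function(indicators,
                             features = c("NCAP", "CAP", "B", "A3", "A2",
                                          "A1", "A")) {
  phi <- vapply(features, function(f) {
    if (is.null(indicators[[f]])) return(NA_real_)
    tryCatch(phiCorrelation(indicators$avalanche, indicators[[f]]),
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(feature = features, phi = unname(phi))
}

#' CAP metrics from an annotation
#'
#' Computes the standard CAP summary: total CAP time (minutes), CAP rate
#' (CAP time over NREM time), number of sequences, cycle counts, mean
#' sequence length, mean phase A and B lengths, per-subtype mean durations
#' and shares of CAP time.
#'
#' @param cap a \linkS4class{CapAnnotation}
#' @param hyp the \linkS4class{Hypnogram} providing NREM time
#' @param minCycles minimum A-B cycles for a CAP sequence
#' @return a list of named metrics
#' @export
capMetrics <- function(cap, hyp, minCycles = 2L) {
  stopifnot(is(cap, "CapAnnotation"), is(hyp, "Hypnogram"))
  nremTime <- sum(hyp@epochStages %in% c("N1", "N2", "N3")) * hyp@epochLength
  if (nremTime == 0) stop("hypnogram contains no NREM sleep")
  seqs <- .capSequences(cap, minCycles = minCycles)
  capTime <- if (nrow(seqs$spans)) sum(seqs$spans[, 2] - seqs$spans[, 1]) else 0
  ph <- capPhases(cap)
  inSeq <- sort(unlist(seqs$groups))
  phSeq <- ph[inSeq, , drop = FALSE]
  isA <- phSeq$label %in% c("A1", "A2", "A3")
  subtypeStats <- lapply(c(A1 = "A1", A2 = "A2", A3 = "A3"), function(s) {
    d <- phSeq$duration_s[phSeq$label == s]
    list(n = length(d),
         meanDuration = if (length(d)) mean(d) else NA_real_,
         timeShareOfCAP = if (capTime > 0) sum(d) / capTime else NA_real_)
  })
  list(capTimeMin = capTime / 60,
       capRate = capTime / nremTime,
       nSequences = nrow(seqs$spans),
       cycleCounts = seqs$cycleCounts,
       totalCycles = sum(seqs$cycleCounts),
       meanSequenceLengthMin = if (nrow(seqs$spans))
         mean(seqs$spans[, 2] - seqs$spans[, 1]) / 60 else NA_real_,
       meanPhaseALength = if (any(isA)) mean(phSeq$duration_s[isA])
                          else NA_real_,
       meanPhaseBLength = if (any(!isA)) mean(phSeq$duration_s[!isA])
                          else NA_real_,
       subtypes = subtypeStats)
}
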