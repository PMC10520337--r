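## Interval helpers. All time intervals are half-open [start, end) in seconds;
## sample indices are 1-based with sample i covering [ (i-1)/fs, i/fs ).

.checkIntervals <- function(intervals) {
  if (is.null(intervals) || length(intervals) == 0) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (is.data.frame(intervals)) intervals <- as.matrix(intervals[, 1:2])
  if (is.vector(intervals) && length(intervals) == 2)
    intervals <- matrix(intervals, ncol = 2)
  if (!is.matrix(intervals) || ncol(intervals) != 2)
    stop("intervals must be a 2-column matrix or data.frame (start_s, end_s)")
  storage.mode(intervals) <- "double"
  if (any(intervals[, 2] <= intervals[, 1]))
    stop("interval end must exceed start")
  colnames(intervals) <- c("start", "end")
  intervals[order(intervals[, 1]), , drop = FALSE]
}

## Merge overlapping/abutting half-open intervals.
.reduceIntervals <- function(intervals) {
  intervals <- .checkIntervals(intervals)
  n <- nrow(intervals)
  if (n <= 1) return(intervals)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("start", "end")))
  k <- 1L
  out[1, ] <- intervals[1, ]
  for (i in 2:n) {
    if (intervals[i, 1] <= out[k, 2]) {
      out[k, 2] <- max(out[k, 2], intervals[i, 2])
    } else {
      k <- k + 1L
      out[k, ] <- intervals[i, ]
    }
  }
  out[seq_len(k), , drop = FALSE]
}

.intervalUnionLength <- function(intervals) {
  r <- .reduceIntervals(intervals)
  if (nrow(r) == 0) return(0)
  sum(r[, 2] - r[, 1])
}

## Samples whose half-open support [ (i-1)/fs, i/fs ) starts inside any
## interval: i such that start <= (i-1)/fs < end.
.intervalsToSamples <- function(intervals, fs, nSamples) {
  intervals <- .checkIntervals(intervals)
  idx <- logical(nSamples)
  for (i in seq_len(nrow(intervals))) {
    from <- max(1L, floor(intervals[i, 1] * fs + 1e-9) + 1L)
    to <- min(nSamples, ceiling(intervals[i, 2] * fs - 1e-9))
    if (from <= to) idx[from:to] <- TRUE
  }
  idx
}

## Pairwise overlap length between one interval and a set of intervals.
.overlapLengths <- function(interval, intervals) {
  if (nrow(intervals) == 0) return(numeric(0))
  pmax(0, pmin(interval[2], intervals[, 2]) - pmax(interval[1], intervals[, 1]))
}

## Maximal runs of TRUE in a logical vector -> matrix of (start, end) sample
## indices, end inclusive.
.logicalRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
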