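#' Simulate a Galton-Watson branching process
#'
#' Generates avalanches from a fully connected mean-field branching process
#' with Poisson offspring. Each avalanche starts from a single active unit
#' (generation 0); at each generation every active unit independently spawns
#' a Poisson(\code{offspringMean}) number of descendants, so the number of
#' activations in the next generation is Poisson(offspringMean * Z). An
#' avalanche ends at extinction, when the number of simultaneous activations
#' reaches \code{nUnits} (finite-size absorption: the generation count is
#' clamped to \code{nUnits} and the avalanche stops), or after
#' \code{maxGenerations} generations.
#'
#' At \code{offspringMean = 1} (the critical point) the process is in the
#' mean-field directed percolation universality class: sizes follow
#' P(s) ~ s^-3/2, durations P(T) ~ T^-2, and mean size scales as T^2.
#'
#' @param offspringMean expected descendants per active unit (>= 0)
#' @param nUnits system size; avalanches absorb at this many simultaneous
#'   activations
#' @param nAvalanches number of avalanches to simulate
#' @param maxGenerations hard cap on generations per avalanche
#' @param seed integer seed; the simulation is bit-reproducible given the seed
#' @param dtStep seconds per generation, stored for conversion to a time axis
#' @return an \linkS4class{AvalancheSample}
#' @examples
#' av <- simulateBranchingProcess(1, nAvalanches = 1000, seed = 1)
#' mean(avalancheSizes(av))
#' @export
simulateBranchingProcess <- function(offspringMean, nUnits = 10000L,
                                     nAvalanches = 1000L,
                                     maxGenerations = 1000L, seed = NULL,
                                     dtStep = 0.01) {
  if (offspringMean < 0) stop("offspringMean must be >= 0")
  if (nUnits < 2) stop("nUnits must be >= 2")
  if (nAvalanches < 1) stop("nAvalanches must be >= 1")
  if (offspringMean > 1 && (!is.finite(maxGenerations) || maxGenerations < 1))
    stop("offspringMean > 1 requires a finite maxGenerations cap ",
         "(supercritical runs need not terminate)")
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(nAvalanches)
  ## Cohort simulation, one vectorized Poisson draw per generation: the
  ## offspring of Z parents is Poisson(offspringMean * Z).
  aliveIdx <- seq_len(n)
  z <- rep(1L, n)                       # generation 0: the seeds
  countsChunks <- list(z)
  idChunks <- list(aliveIdx)
  gen <- 0L
  while (length(aliveIdx) > 0 && gen < maxGenerations) {
    gen <- gen + 1L
    znext <- rpois(length(z), offspringMean * as.numeric(z))
    hitCap <- znext >= nUnits
    znext[hitCap] <- nUnits
    keep <- znext > 0L
    if (any(keep)) {
      countsChunks[[gen + 1L]] <- znext[keep]
      idChunks[[gen + 1L]] <- aliveIdx[keep]
    }
    ## avalanches that hit the cap record this generation, then absorb
    cont <- keep & !hitCap
    aliveIdx <- aliveIdx[cont]
    z <- znext[cont]
  }
  counts <- unlist(countsChunks, use.names = FALSE)
  ids <- unlist(idChunks, use.names = FALSE)
  ord <- order(ids)                     # generations appended in order, so a
  counts <- counts[ord]                 # stable sort keeps them sequential
  ids <- ids[ord]
  generationCounts <- split(counts, factor(ids, levels = seq_len(n)))
  names(generationCounts) <- NULL
  sizes <- as.numeric(vapply(generationCounts, sum, numeric(1)))
  durations <- lengths(generationCounts)
  new("AvalancheSample", sizes = sizes, durations = as.integer(durations),
      generationCounts = generationCounts, offspringMean = offspringMean,
      dtStep = dtStep)
}

#' Sample a bounded continuous power law
#'
#' Inverse-CDF draws from p(x) proportional to x^-exponent on [xmin, xmax].
#'
#' @param exponent power-law exponent (> 1 when xmax is infinite)
#' @param xmin,xmax support bounds, 0 < xmin < xmax
#' @param n number of draws
#' @param seed integer seed
#' @return numeric vector of n draws in [xmin, xmax]
#' @export
samplePowerLaw <- function(exponent, xmin, xmax, n, seed = NULL) {
  if (xmin <= 0 || xmax <= xmin) stop("need xmax > xmin > 0")
  if (!is.finite(xmax) && exponent <= 1)
    stop("exponent <= 1 with infinite xmax is not normalizable")
  if (n == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  if (abs(exponent - 1) < 1e-12) {
    xmin * (xmax / xmin)^u
  } else {
    g <- 1 - exponent
    if (is.finite(xmax)) {
      (xmin^g + u * (xmax^g - xmin^g))^(1 / g)
    } else {
      xmin * (1 - u)^(1 / g)
    }
  }
}

#' Analytic CDF of the bounded power law
#'
#' CDF of p(x) proportional to x^-exponent on [xmin, xmax]; used as the
#' reference distribution for goodness-of-fit.
#'
#' @param x quantiles
#' @inheritParams samplePowerLaw
#' @return numeric vector of probabilities
#' @export
powerLawCDF <- function(x, exponent, xmin, xmax) {
  x <- pmin(pmax(x, xmin), xmax)
  if (abs(exponent - 1) < 1e-12) {
    log(x / xmin) / log(xmax / xmin)
  } else {
    g <- 1 - exponent
    if (is.finite(xmax)) {
      (x^g - xmin^g) / (xmax^g - xmin^g)
    } else {
      1 - (x / xmin)^g
    }
  }
}

#' @describeIn estimateBranchingParameter mean Z2/Z1 over avalanches with
#'   at least one descendant generation (seed = generation 0); Z2 counts as 0
#'   for avalanches that die after generation 1.
#' @export
setMethod("estimateBranchingParameter", "AvalancheSample", function(x, ...) {
  use <- x@durations >= 2L
  if (!any(use))
    stop("no avalanche spans two generations; cannot estimate the branching parameter")
  gc <- x@generationCounts[use]
  z1 <- vapply(gc, function(g) as.numeric(g[2L]), numeric(1))
  z2 <- vapply(gc, function(g) if (length(g) >= 3L) as.numeric(g[3L]) else 0,
               numeric(1))
  list(sigmaHat = mean(z2 / z1), binWidth = NA_real_,
       nAvalanchesUsed = sum(use))
})
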