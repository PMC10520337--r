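#' Read a hypnogram from TSV
#'
#' Expects two tab-separated columns with a header: \code{epoch_index} and
#' \code{stage} (values W, N1, N2, N3, REM).
#'
#' @param path file path
#' @return a \linkS4class{Hypnogram}
#' @export
readHypnogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "stage"))
  if (!all(c("epoch_index", "stage") %in% names(dt)))
    stop("hypnogram TSV must have columns epoch_index and stage")
  bad <- which(!dt$stage %in% .STAGES)
  if (length(bad))
    stop("unknown stage label '", dt$stage[bad[1]], "' at line ", bad[1] + 1L)
  dt <- dt[order(dt$epoch_index), ]
  new("Hypnogram", epochStages = dt$stage, epochLength = 30, startS = 0)
}

#' Write a hypnogram to TSV
#' @param hyp a \linkS4class{Hypnogram}
#' @param path output path
#' @return invisibly, the path
#' @export
writeHypnogram <- function(hyp, path) {
  stopifnot(is(hyp, "Hypnogram"))
  dt <- data.table::data.table(
    epoch_index = seq_along(hyp@epochStages) - 1L,
    stage = hyp@epochStages)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read CAP annotations from CSV
#'
#' Expects comma-separated columns \code{onset_s}, \code{duration_s},
#' \code{label} (A1, A2, A3, B). Phases are sorted and overlap-checked;
#' overlapping phases are an error. Phases with durations outside the
#' scoring bounds [2, 60] s are loaded with a warning, and phases lying
#' outside NREM sleep (against the supplied hypnogram) are dropped with a
#' warning.
#'
#' @param path file path
#' @param hyp optional \linkS4class{Hypnogram} for the NREM check
#' @return a \linkS4class{CapAnnotation}
#' @export
readCapAnnotations <- function(path, hyp = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  if (nrow(dt) == 0)
    return(new("CapAnnotation",
               phases = data.frame(onset_s = numeric(0),
                                   duration_s = numeric(0),
                                   label = character(0))))
  if (!all(c("onset_s", "duration_s", "label") %in% names(dt)))
    stop("CAP CSV must have columns onset_s, duration_s, label")
  ph <- as.data.frame(dt)[, c("onset_s", "duration_s", "label")]
  ph <- ph[order(ph$onset_s), , drop = FALSE]
  ends <- ph$onset_s + ph$duration_s
  if (nrow(ph) > 1 && any(ph$onset_s[-1] < ends[-nrow(ph)] - 1e-9))
    stop("overlapping CAP phases")
  outOfBounds <- ph$duration_s < 2 | ph$duration_s > 60
  if (any(outOfBounds))
    warning(sum(outOfBounds), " phase(s) with duration outside [2, 60] s ",
            "retained")
  if (!is.null(hyp)) {
    mid <- ph$onset_s + ph$duration_s / 2
    stage <- .stageAt(hyp, mid)
    nonNrem <- !stage %in% c("N1", "N2", "N3")
    if (any(nonNrem)) {
      warning(sum(nonNrem), " phase(s) outside NREM dropped")
      ph <- ph[!nonNrem, , drop = FALSE]
    }
  }
  rownames(ph) <- NULL
  new("CapAnnotation", phases = ph)
}

#' Write CAP annotations to CSV
#' @param cap a \linkS4class{CapAnnotation}
#' @param path output path
#' @return invisibly, the path
#' @export
writeCapAnnotations <- function(cap, path) {
  stopifnot(is(cap, "CapAnnotation"))
  data.table::fwrite(data.table::as.data.table(capPhases(cap)), path,
                     sep = ",")
  invisible(path)
}

#' Write an avalanche catalog to TSV
#' @param catalog an \linkS4class{AvalancheCatalog}
#' @param path output path
#' @return invisibly, the path
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "AvalancheCatalog"))
  av <- avalanches(catalog)
  data.table::fwrite(
    data.table::as.data.table(
      av[, c("onset_s", "offset_s", "duration_s", "size", "n_channels")]),
    path, sep = "\t")
  invisible(path)
}
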