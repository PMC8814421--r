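#' Single-cell analysis configuration
#'
#' @param controlThreshold Internal-control intensity above which (strict
#'   `>`) a cell counts as control-expressing; default 256, i.e. 8 in log2
#'   units, chosen from the clearly bimodal control histograms.
#' @param reporterThreshold Reporter threshold for the expressing-cell
#'   fraction; defaults to the same 256 (reporter bimodality is imperfect,
#'   so the threshold-free conditional mean is reported alongside).
#' @param diskRadius Disk ROI radius in pixels.
#' @param logFloor Floor applied before log2 (default 1).
#' @return A [SingleCellConfig-class].
#' @export
singleCellConfig <- function(controlThreshold = 256,
                             reporterThreshold = 256,
                             diskRadius = 5, logFloor = 1) {
  new("SingleCellConfig", controlThreshold = controlThreshold,
      reporterThreshold = reporterThreshold, diskRadius = diskRadius,
      logFloor = logFloor)
}

#' Split cells by internal-control expression
#'
#' Strict inequality: a cell is control-expressing iff
#' `control_mean > controlThreshold`, so a cell exactly at 256 is
#' non-expressing.
#'
#' @param cells data.frame with a `control_mean` column.
#' @param cfg A [SingleCellConfig-class].
#' @return List with elements `expressing` and `nonExpressing` (disjoint,
#'   exhaustive).
#' @export
classifyControlExpressing <- function(cells, cfg = singleCellConfig()) {
  ex <- cells$control_mean > cfg@controlThreshold
  list(expressing = cells[ex, , drop = FALSE],
       nonExpressing = cells[!ex, , drop = FALSE])
}

#' Floored log2 intensity
#'
#' `log2(max(value, logFloor))`: with the default floor of 1, zeros map to
#' 0 and 256 maps to exactly 8.
#'
#' @param value Intensity value(s), non-negative.
#' @param cfg A [SingleCellConfig-class].
#' @return Log2-transformed intensities (bits).
#' @export
log2Intensity <- function(value, cfg = singleCellConfig()) {
  log2(pmax(value, cfg@logFloor))
}

#' Reporter-on-control regression among expressing cells
#'
#' Ordinary least squares of reporter intensity on internal-control
#' intensity, fit by default on raw intensities (with a log2-space option).
#' A decreased slope with an intact relationship is the graded-decrease
#' signature; mosaicism alone leaves the slope unchanged.
#'
#' @param cells data.frame with `reporter_mean` and `control_mean`,
#'   already restricted to control-expressing cells.
#' @param logSpace Fit on floored log2 intensities instead of raw.
#' @param cfg Used for the log floor when `logSpace = TRUE`.
#' @return Named vector `c(intercept, slope)`.
#' @export
expressionRegression <- function(cells, logSpace = FALSE,
                                 cfg = singleCellConfig()) {
  if (nrow(cells) < 3) stop("need at least 3 cells for a regression")
  x <- cells$control_mean
  y <- cells$reporter_mean
  if (logSpace) {
    x <- log2Intensity(x, cfg)
    y <- log2Intensity(y, cfg)
  }
  if (stats::var(x) == 0)
    stop("control intensities are constant; regression is degenerate")
  fit <- stats::lm(y ~ x)
  c(intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]))
}

.singleCellSummary <- function(cells, cfg) {
  parts <- classifyControlExpressing(cells, cfg)
  ex <- parts$expressing
  if (nrow(ex) == 0)
    stop("no control-expressing cells after filtering")
  repOn <- ex$reporter_mean > cfg@reporterThreshold
  both <- ex[repOn, , drop = FALSE]
  condMean <- if (nrow(both) == 0) NA_real_ else
    mean(log2Intensity(both$reporter_mean, cfg) -
           log2Intensity(both$control_mean, cfg))
  list(n_cells = nrow(cells),
       n_control_expressing = nrow(ex),
       fraction_reporter_expressing = mean(repOn),
       conditional_log_ratio_mean = condMean)
}

#' Mosaicism versus graded-decrease decomposition
#'
#' For wildtype and mutant cell sets, reports (i) the fraction of
#' control-expressing cells whose reporter also exceeds the reporter
#' threshold — the mosaicism axis — and (ii) the mean log2(reporter/control)
#' among cells above threshold in both channels — the graded axis, computed
#' on doubly-expressing cells so that silent cells at baseline do not drag
#' the conditional mean. A pure increase in mosaicism moves the fraction but
#' not the conditional ratio; a pure graded decrease moves the conditional
#' ratio (halving the per-cell level costs one bit) but not the fraction.
#'
#' @param wtCells,mutCells data.frames of per-cell measurements
#'   (`reporter_mean`, `control_mean`).
#' @param cfg A [SingleCellConfig-class].
#' @return List with per-construct summaries (`wildtype`, `mutant`) and
#'   `delta_fraction`, `delta_conditional_log_ratio` (mutant - wildtype).
#' @export
mosaicismGradedSummary <- function(wtCells, mutCells,
                                   cfg = singleCellConfig()) {
  wt <- .singleCellSummary(wtCells, cfg)
  mut <- .singleCellSummary(mutCells, cfg)
  list(wildtype = wt, mutant = mut,
       delta_fraction = mut$fraction_reporter_expressing -
         wt$fraction_reporter_expressing,
       delta_conditional_log_ratio = mut$conditional_log_ratio_mean -
         wt$conditional_log_ratio_mean)
}

#' Disk-ROI means from a 2D image
#'
#' Mean intensity within disks of uniform radius centered on given
#' coordinates (pixel-center inclusion: a pixel belongs to the disk iff its
#' center lies within `radius` of the disk center).
#'
#' @param image Y x X numeric matrix.
#' @param centers data.frame with columns `x`, `y`.
#' @param radius Disk radius in pixels.
#' @return Numeric vector of disk means.
#' @export
diskMeans <- function(image, centers, radius) {
  vapply(seq_len(nrow(centers)), function(i) {
    cx <- centers$x[i]; cy <- centers$y[i]
    cols <- max(1L, floor(cx - radius)):min(ncol(image), ceiling(cx + radius))
    rows <- max(1L, floor(cy - radius)):min(nrow(image), ceiling(cy + radius))
    grid <- expand.grid(row = rows, col = cols)
    inside <- (grid$col - cx)^2 + (grid$row - cy)^2 <= radius^2
    if (!any(inside)) stop("disk encloses no pixel centers")
    mean(image[cbind(grid$row[inside], grid$col[inside])])
  }, numeric(1))
}
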