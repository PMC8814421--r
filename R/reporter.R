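#' Construct an image stack
#'
#' @param voxels 4-d array (channel, z, y, x) with channel dimnames, or a
#'   list of Z x Y x X arrays (one per channel, named).
#' @param channelRoles Named character mapping roles (`reporter`, `control`,
#'   optionally `counterstain`) to channel names.
#' @return An [ImageStack-class].
#' @export
imageStack <- function(voxels, channelRoles) {
  if (is.list(voxels)) {
    nms <- names(voxels)
    d <- dim(voxels[[1]])
    arr <- array(0, c(length(voxels), d), dimnames = c(list(nms),
                                                       vector("list", 3)))
    for (i in seq_along(voxels)) arr[i, , , ] <- voxels[[i]]
    voxels <- arr
  }
  new("ImageStack", voxels = voxels, channelRoles = channelRoles)
}

#' Construct an ROI set
#'
#' @param whole,primary,secondary Polygons as n x 2 matrices of (x, y)
#'   vertices; lineage polygons default to empty.
#' @return An [ROISet-class].
#' @export
roiSet <- function(whole, primary = matrix(numeric(), 0, 2),
                   secondary = matrix(numeric(), 0, 2)) {
  new("ROISet", whole = whole, primary = primary, secondary = secondary)
}

#' Sum-project a stack channel
#'
#' Flattens the Z dimension by summation, conserving total intensity
#' (unlike a max projection, no photon counts are discarded).
#'
#' @param stack An [ImageStack-class].
#' @param channel Channel name, index, or role (`"reporter"`, `"control"`,
#'   `"counterstain"`).
#' @return A Y x X matrix.
#' @export
sumProject <- function(stack, channel) {
  v <- stack@voxels
  ch <- channel
  if (is.character(ch) && ch %in% names(stack@channelRoles))
    ch <- stack@channelRoles[[ch]]
  if (is.character(ch)) {
    if (!ch %in% dimnames(v)[[1]])
      stop(sprintf("no channel '%s' in stack", channel))
    ch <- match(ch, dimnames(v)[[1]])
  }
  if (ch < 1 || ch > dim(v)[1]) stop("channel index out of range")
  img <- apply(v[ch, , , , drop = FALSE], c(3, 4), sum)
  dimnames(img) <- NULL
  img
}

# even-odd (crossing-number) point-in-polygon test at pixel centers;
# px, py are vectors of point coordinates, poly an n x 2 (x, y) matrix
.pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Mean intensity within a polygonal ROI
#'
#' A pixel belongs to the ROI iff its center falls inside the polygon under
#' the even-odd rule; pixel (row, col) has its center at (x = col, y = row).
#'
#' @param image Y x X numeric matrix (e.g. from [sumProject()]).
#' @param polygon n x 2 matrix of (x, y) vertices.
#' @return Mean of the enclosed pixel values.
#' @export
roiMean <- function(image, polygon) {
  stopifnot(is.matrix(image), is.matrix(polygon), ncol(polygon) == 2)
  # restrict the center test to the polygon's bounding box
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  cols <- max(1L, floor(xr[1])):min(ncol(image), ceiling(xr[2]))
  rows <- max(1L, floor(yr[1])):min(nrow(image), ceiling(yr[2]))
  if (length(cols) == 0 || length(rows) == 0 || xr[1] > ncol(image) ||
      yr[1] > nrow(image) || xr[2] < 1 || yr[2] < 1)
    stop("polygon encloses no pixel centers")
  grid <- expand.grid(row = rows, col = cols)
  inside <- .pointsInPolygon(grid$col, grid$row, polygon)
  if (!any(inside)) stop("polygon encloses no pixel centers")
  mean(image[cbind(grid$row[inside], grid$col[inside])])
}

#' Per-embryo dual-reporter ratio
#'
#' The electroporation-efficiency-corrected expression value: reporter mean
#' divided by internal-control mean. Any per-embryo multiplicative factor
#' (delivery efficiency, staining intensity) cancels.
#'
#' @param reporterMean,controlMean ROI mean intensities (vectorized).
#' @return `reporterMean / controlMean`.
#' @export
embryoRatio <- function(reporterMean, controlMean) {
  if (any(controlMean <= 0))
    stop("control mean must be positive; embryos without internal-control signal are excluded upstream")
  reporterMean / controlMean
}

#' Normalize an experiment to its wildtype mean
#'
#' Computes per-embryo raw ratios and scales them, within each replicate
#' (one electroporation day = one experiment), by the mean raw ratio of the
#' wildtype construct in that replicate, so the wildtype mean is exactly 1
#' per replicate. If lineage columns (`reporter_primary`, `control_primary`,
#' `reporter_secondary`, `control_secondary`) are present, per-lineage
#' normalized ratios and the raw primary/secondary ratio are added.
#'
#' @param measurements data.frame with columns `embryo_id`, `replicate_id`,
#'   `construct_id`, `reporter_mean`, `control_mean` and optional lineage
#'   columns.
#' @param wildtypeId Construct id of the wildtype anchor.
#' @return The input with columns `raw_ratio`, `normalized_ratio` and,
#'   when lineage data are present, `primary_ratio`, `secondary_ratio`,
#'   `primary_secondary_ratio`.
#' @export
normalizeExperiment <- function(measurements, wildtypeId) {
  m <- measurements
  need <- c("embryo_id", "replicate_id", "construct_id",
            "reporter_mean", "control_mean")
  if (!all(need %in% names(m)))
    stop("measurements must have columns ",
         paste(need, collapse = ", "))
  m$raw_ratio <- embryoRatio(m$reporter_mean, m$control_mean)
  hasLineage <- all(c("reporter_primary", "control_primary",
                      "reporter_secondary", "control_secondary") %in%
                      names(m))
  if (hasLineage) {
    m$raw_primary <- embryoRatio(m$reporter_primary, m$control_primary)
    m$raw_secondary <- embryoRatio(m$reporter_secondary,
                                   m$control_secondary)
    m$primary_secondary_ratio <- m$raw_primary / m$raw_secondary
  }
  m$normalized_ratio <- NA_real_
  if (hasLineage) m$primary_ratio <- m$secondary_ratio <- NA_real_
  for (rep in unique(m$replicate_id)) {
    sel <- m$replicate_id == rep
    wt <- sel & m$construct_id == wildtypeId
    if (!any(wt))
      stop(sprintf("replicate '%s' has no wildtype ('%s') embryos", rep,
                   wildtypeId))
    m$normalized_ratio[sel] <- m$raw_ratio[sel] / mean(m$raw_ratio[wt])
    if (hasLineage) {
      m$primary_ratio[sel] <- m$raw_primary[sel] / mean(m$raw_primary[wt])
      m$secondary_ratio[sel] <-
        m$raw_secondary[sel] / mean(m$raw_secondary[wt])
    }
  }
  m
}

#' Primary/secondary lineage expression ratio
#'
#' The per-embryo ratio of the reporter/control ratio in the primary
#' (anterior 32-cell) notochord to that in the secondary (posterior 8-cell)
#' notochord; 1 means equal lineage expression, values above 1 mean the
#' secondary lineage is more strongly affected.
#'
#' @param reporterPrimary,controlPrimary,reporterSecondary,controlSecondary
#'   Lineage ROI means (vectorized).
#' @return The lineage ratio.
#' @export
primarySecondaryRatio <- function(reporterPrimary, controlPrimary,
                                  reporterSecondary, controlSecondary) {
  embryoRatio(reporterPrimary, controlPrimary) /
    embryoRatio(reporterSecondary, controlSecondary)
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Pairwise construct comparisons with BH adjustment
#'
#' Two-sample t statistics for every unordered pair of constructs using a
#' single pooled standard deviation estimated across all groups (the
#' behavior of `pairwise.t.test`'s default), with Benjamini-Hochberg
#' adjustment over the full pair set and significance stars at
#' 0.05 / 0.01 / 0.001 on the adjusted p-values. A per-pair Welch option is
#' available but off by default.
#'
#' @param values Numeric vector of (normalized) per-embryo values.
#' @param groups Construct id per value.
#' @param welch If TRUE, per-pair Welch t-tests instead of the pooled-SD
#'   statistic.
#' @return data.frame with columns `group1`, `group2`, `t`, `df`, `raw_p`,
#'   `adjusted_p`, `stars`.
#' @export
pairwiseTests <- function(values, groups, welch = FALSE) {
  groups <- as.character(groups)
  ids <- unique(groups)
  ns <- table(groups)[ids]
  if (any(ns < 2)) stop("every group needs at least 2 values")
  k <- length(ids)
  if (k < 2) stop("need at least 2 groups")
  means <- tapply(values, groups, mean)[ids]
  vars <- tapply(values, groups, stats::var)[ids]
  N <- length(values)
  pooled <- sum((ns - 1) * vars) / (N - k)
  pairs <- utils::combn(ids, 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t = NA_real_, df = NA_real_, raw_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (welch) {
      tt <- stats::t.test(values[groups == a], values[groups == b])
      res$t[i] <- unname(tt$statistic)
      res$df[i] <- unname(tt$parameter)
      res$raw_p[i] <- tt$p.value
    } else {
      se <- sqrt(pooled * (1 / ns[[a]] + 1 / ns[[b]]))
      tstat <- if (se == 0) 0 else (means[[a]] - means[[b]]) / se
      res$t[i] <- tstat
      res$df[i] <- N - k
      res$raw_p[i] <- 2 * stats::pt(-abs(tstat), N - k)
    }
  }
  res$adjusted_p <- stats::p.adjust(res$raw_p, method = "BH")
  res$stars <- .stars(res$adjusted_p)
  res
}
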