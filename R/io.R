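#' Read a per-embryo measurement table
#'
#' TSV with columns `embryo_id`, `replicate_id`, `construct_id`,
#' `reporter_mean`, `control_mean` and optional lineage columns
#' (`reporter_primary`, `control_primary`, `reporter_secondary`,
#' `control_secondary`), the pre-measured route that bypasses images.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readMeasurementTable <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "replicate_id", "construct_id",
            "reporter_mean", "control_mean")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0)
    stop("measurement table lacks columns: ",
         paste(missing, collapse = ", "))
  m
}

#' Read a per-cell measurement table
#'
#' TSV with columns `cell_id`, `embryo_id`, `construct_id`,
#' `reporter_mean`, `control_mean`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readCellTable <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "embryo_id", "construct_id", "reporter_mean",
            "control_mean")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0)
    stop("cell table lacks columns: ", paste(missing, collapse = ", "))
  m
}

#' Write and read ROI polygons as JSON
#'
#' @param rois An [ROISet-class].
#' @param path JSON path.
#' @export
writeROISet <- function(rois, path) {
  obj <- lapply(c("whole", "primary", "secondary"), function(nm) {
    p <- slot(rois, nm)
    if (nrow(p) == 0) NULL else list(x = p[, 1], y = p[, 2])
  })
  names(obj) <- c("whole", "primary", "secondary")
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeROISet
#' @export
readROISet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  get <- function(nm) {
    if (length(obj[[nm]]$x) == 0) return(matrix(numeric(), 0, 2))
    cbind(x = obj[[nm]]$x, y = obj[[nm]]$y)
  }
  roiSet(get("whole"), get("primary"), get("secondary"))
}

#' Write and read an image stack as multi-page TIFF
#'
#' Pages are ordered channel-fastest within z (c1z1, c2z1, c1z2, ...).
#' Intensities are stored as 32-bit float scaled into [0, 1] by `scale`
#' (default the stack maximum); pass the same scale when reading to recover
#' the original values.
#'
#' @param stack An [ImageStack-class].
#' @param path TIFF path.
#' @param scale Intensity mapped to 1.0 in the file.
#' @return `writeStackTIFF` invisibly returns the scale used;
#'   `readStackTIFF` returns an [ImageStack-class].
#' @export
writeStackTIFF <- function(stack, path, scale = max(stack@voxels, 1)) {
  v <- stack@voxels / scale
  d <- dim(v)
  pages <- list()
  for (z in seq_len(d[2]))
    for (ch in seq_len(d[1]))
      pages[[length(pages) + 1L]] <- v[ch, z, , ]
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' @rdname writeStackTIFF
#' @param channelNames Channel names, in page order within each z.
#' @param channelRoles Role mapping for the resulting stack.
#' @export
readStackTIFF <- function(path, channelNames, channelRoles, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(channelNames)
  if (length(pages) %% nch != 0)
    stop("page count is not a multiple of the channel count")
  nz <- length(pages) / nch
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  v <- array(0, c(nch, nz, ny, nx),
             dimnames = c(list(channelNames), vector("list", 3)))
  k <- 1L
  for (z in seq_len(nz))
    for (ch in seq_len(nch)) {
      v[ch, z, , ] <- pages[[k]] * scale
      k <- k + 1L
    }
  new("ImageStack", voxels = v, channelRoles = channelRoles)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path FASTA path.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
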