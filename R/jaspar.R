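#' Read motif count matrices in JASPAR text format
#'
#' Parses the JASPAR 2016/2018 count-matrix dialect: a header line
#' `>ID NAME` followed by four base rows such as `A [ 4 19 0 ... ]`
#' (brackets and base letters optional, as in the older raw dialect —
#' in that case rows are taken in A, C, G, T order). Base rows may appear
#' in any order when labelled; they are normalized to A, C, G, T.
#'
#' @param path Path to a JASPAR-format text file, or a character vector of
#'   its lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return A list of [MotifMatrix-class] objects in file order.
#' @examples
#' txt <- c(">MA0001.1 TOY", "A [ 10 0 ]", "C [ 0 0 ]",
#'          "G [ 0 10 ]", "T [ 0 0 ]")
#' readJaspar(text = txt)
#' @export
readJaspar <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) == 0)
    stop("no JASPAR header lines ('>ID NAME') found")
  bounds <- c(headers, length(lines) + 1L)
  out <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    block <- lines[headers[i]:(bounds[i + 1L] - 1L)]
    out[[i]] <- .parseJasparBlock(block)
  }
  out
}

.parseJasparBlock <- function(block) {
  hdr <- sub("^>\\s*", "", block[1])
  toks <- strsplit(hdr, "\\s+")[[1]]
  motifId <- toks[1]
  factorName <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else ""
  rows <- block[-1]
  if (length(rows) != 4)
    stop(sprintf("motif '%s': expected 4 base rows, found %d",
                 motifId, length(rows)))
  parsed <- vector("list", 4)
  labels <- character(4)
  for (j in seq_len(4)) {
    ln <- rows[j]
    has_label <- grepl("^[ACGTacgt]([^0-9A-Za-z]|$)", ln)
    labels[j] <- if (has_label) toupper(substr(ln, 1, 1)) else DNA_BASES[j]
    body <- if (has_label) sub("^[ACGTacgt]", "", ln) else ln
    body <- gsub("\\[|\\]", " ", body)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
    if (length(vals) == 0 || anyNA(vals))
      stop(sprintf("motif '%s': cannot parse counts in row '%s'", motifId, ln))
    parsed[[j]] <- vals
  }
  if (!setequal(labels, DNA_BASES))
    stop(sprintf("motif '%s': base rows are %s; need one each of A, C, G, T",
                 motifId, paste(labels, collapse = ",")))
  widths <- lengths(parsed)
  if (length(unique(widths)) != 1)
    stop(sprintf("motif '%s': ragged base rows (widths %s)",
                 motifId, paste(widths, collapse = ",")))
  counts <- matrix(NA_real_, 4, widths[1], dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(4)) counts[labels[j], ] <- parsed[[j]]
  new("MotifMatrix", motifId = motifId, factorName = factorName,
      counts = counts)
}

#' @describeIn readJaspar Motif identifier accessor.
#' @param x A `MotifMatrix` or `LogOddsMatrix`.
#' @export
motifId <- function(x) x@motifId

#' @describeIn readJaspar Factor name accessor.
#' @export
factorName <- function(x) x@factorName

#' @describeIn readJaspar Count matrix accessor.
#' @export
motifCounts <- function(x) x@counts

#' @describeIn readJaspar Motif width (number of columns).
#' @export
motifWidth <- function(x) {
  if (is(x, "MotifMatrix")) ncol(x@counts) else ncol(x@scores)
}

setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix %s (%s), width %d\n", object@motifId,
              if (nzchar(object@factorName)) object@factorName else "?",
              ncol(object@counts)))
  print(object@counts)
})
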