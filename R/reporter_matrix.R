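# Reporter matrices: raw protein x channel intensities for one multiplex.

#' Construct a reporter matrix
#'
#' A reporter matrix holds the protein-level TMT reporter intensities of one
#' multiplex: a nonnegative numeric matrix with unique protein identifiers as
#' row names and reporter channel labels as column names.
#'
#' @param multiplex_id Identifier of the multiplex.
#' @param intensities Numeric matrix, proteins x channels, with `rownames`
#'   (protein ids) and `colnames` (channel ids). All values must be finite
#'   and nonnegative; zero is allowed and is treated as missing downstream.
#' @return An object of class `reporter_matrix`.
#' @export
reporter_matrix <- function(multiplex_id, intensities) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("'intensities' must be a numeric matrix")
  }
  ids <- rownames(intensities)
  if (is.null(ids) || is.null(colnames(intensities))) {
    stop("'intensities' needs protein row names and channel column names")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!is.finite(intensities))) {
    stop("intensities contain non-finite values")
  }
  if (any(intensities < 0)) {
    bad <- rownames(which(intensities < 0, arr.ind = TRUE))
    stop("negative intensities for: ",
         paste(unique(bad), collapse = ", "))
  }
  structure(
    list(multiplex_id = as.character(multiplex_id), intensities = intensities),
    class = "reporter_matrix"
  )
}

#' @export
print.reporter_matrix <- function(x, ...) {
  cat("reporter_matrix '", x$multiplex_id, "': ",
      nrow(x$intensities), " proteins x ", ncol(x$intensities),
      " channels\n", sep = "")
  invisible(x)
}

#' Read a reporter matrix from TSV
#'
#' The file has a `protein_id` column followed by one column per reporter
#' channel. Channels are checked against the design entry for the given
#' multiplex; unknown channels, duplicate protein ids and negative
#' intensities are format errors.
#'
#' @param path TSV file path.
#' @param design Multiplex design (see [read_design()]).
#' @param multiplex_id Which multiplex this file belongs to.
#' @return A [reporter_matrix()].
#' @export
read_reporter_matrix <- function(path, design, multiplex_id) {
  if (!file.exists(path)) stop("reporter matrix file not found: ", path)
  validate_design(design)
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"protein_id" %in% names(tab)) {
    stop("reporter matrix file must have a 'protein_id' column: ", path)
  }
  chans <- setdiff(names(tab), "protein_id")
  known <- design$channel[design$multiplex == multiplex_id]
  if (!length(known)) stop("multiplex '", multiplex_id, "' not in design")
  unknown <- setdiff(chans, known)
  if (length(unknown)) {
    stop("channel column(s) not in design for multiplex '", multiplex_id,
         "': ", paste(unknown, collapse = ", "))
  }
  mat <- as.matrix(tab[, chans, drop = FALSE])
  mode(mat) <- "double"
  rownames(mat) <- as.character(tab$protein_id)
  reporter_matrix(multiplex_id, mat)
}

#' Write a reporter matrix to TSV
#'
#' Values are written in decimal text at full double precision so that a
#' write/read round trip is bitwise exact.
#'
#' @param x A [reporter_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reporter_matrix <- function(x, path) {
  stopifnot(inherits(x, "reporter_matrix"))
  out <- data.frame(protein_id = rownames(x$intensities),
                    stringsAsFactors = FALSE)
  for (ch in colnames(x$intensities)) {
    out[[ch]] <- format_full(x$intensities[, ch])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# full-precision decimal rendering of doubles (round-trips through as.numeric)
format_full <- function(x) {
  formatC(x, format = "g", digits = 17)
}

#' Write a result table to TSV
#'
#' Generic writer for the pipeline's result data frames; numeric columns are
#' written at full precision.
#'
#' @param tab A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tab, path) {
  out <- tab
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- format_full(out[[nm]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
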