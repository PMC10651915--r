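#' Round half away from zero to integer percent
#'
#' Standard "commercial" rounding: 0.5 always rounds up in magnitude.
#' Used for all reported integer percentages so that printed summaries
#' are stable across platforms (base \code{round()} rounds half to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Write a data frame as a plain TSV file
#'
#' @param x data frame.
#' @param path output path.
#' @param row_names write row names as a first column (default FALSE).
#' @return invisibly, \code{path}.
#' @export
write_tsv <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

#' Read a plain TSV file written by this package
#'
#' @param path input path.
#' @return data frame with character columns left as-is.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

## canonical group levels for the four-condition reference design
GROUP_LEVELS <- c("WT_SELF", "WT_HOST", "MUT_SELF", "MUT_HOST")

group_of <- function(strain, confrontation) {
  paste(toupper(strain), toupper(confrontation), sep = "_")
}
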