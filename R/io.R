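#' Write a pipeline table to CSV
#'
#' Fixed dialect throughout the pipeline: comma separated, header row, UTF-8,
#' ISO-8601 dates, `NA` for missing values, no row names.
#'
#' @param x Data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stage_csv <- function(x, path) {
  for (j in seq_along(x)) if (inherits(x[[j]], "Date"))
    x[[j]] <- format(x[[j]], "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pipeline CSV written by [write_stage_csv()]
#'
#' Columns named `date` (or ending in `_date`) are parsed back to `Date`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_stage_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  datecols <- grep("(^date$)|(_date$)", names(x))
  for (j in datecols) x[[j]] <- as.Date(x[[j]])
  x
}
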