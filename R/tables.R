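#' Write result tables to CSV
#'
#' All pipeline results are plain data frames (one row per trace sample,
#' transient, event, wave or terminal).  List columns (e.g. event member
#' lists) are JSON-encoded in the CSV so that [read_tables()] restores an
#' equal object.
#'
#' @param x a data.frame, or a named list of data.frames.
#' @param path output CSV path (for a list, a directory; one
#'   `<name>.csv` file per table).
#' @export
write_tables <- function(x, path) {
  if (is.data.frame(x)) {
    df <- x
    for (cn in names(df)) {
      if (is.list(df[[cn]]))
        df[[cn]] <- vapply(df[[cn]], function(v)
          as.character(jsonlite::toJSON(v)), character(1))
    }
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  stopifnot(is.list(x), !is.null(names(x)))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (nm in names(x)) write_tables(x[[nm]], file.path(path, paste0(nm, ".csv")))
  invisible(path)
}

#' Read a result table written by [write_tables()]
#'
#' @param path CSV path.
#' @param list_cols character vector of column names to decode from JSON
#'   back into list columns.
#' @return a data.frame.
#' @export
read_tables <- function(path, list_cols = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in intersect(list_cols, names(df)))
    df[[cn]] <- lapply(df[[cn]], function(s)
      jsonlite::fromJSON(s, simplifyVector = TRUE))
  df
}
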