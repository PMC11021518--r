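## Cell-table IO: comma-delimited text, UTF-8, one cell per row, fixed
## leading columns (cell_id, sample_id, strain_id, replicate, length_um,
## n_nuclei, is_background, signal_HPG, signal_AHA); extra columns follow.

.CELL_COLS <- c("cell_id", "sample_id", "strain_id", "replicate",
                "length_um", "n_nuclei", "is_background",
                "signal_HPG", "signal_AHA")

#' Write a cell table to delimited text
#'
#' @param tab Cell table.
#' @param path Output path (CSV, header row, UTF-8).
#' @export
writeCellTable <- function(tab, path) {
  miss <- setdiff(.CELL_COLS, names(tab))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  ord <- c(.CELL_COLS, setdiff(names(tab), .CELL_COLS))
  write.csv(tab[, ord, drop = FALSE], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cell table written by [writeCellTable()]
#'
#' @param path Input path.
#' @return The cell table as a data.frame.
#' @export
readCellTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(.CELL_COLS, names(tab))
  if (length(miss))
    stop("file is not a cell table; missing: ", paste(miss, collapse = ", "))
  tab$is_background <- as.logical(tab$is_background)
  tab
}
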