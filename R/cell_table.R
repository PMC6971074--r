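#' Write a single-cell table to CSV
#'
#' The single-cell table is the pipeline's hub format: one row per
#' segmented cell with its centroid (micrometres), area (square
#' micrometres) and the mean intensity of every marker. Columns are written
#' in the fixed order `cell_id, case_id, x_um, y_um, area_um2`, then the
#' markers in panel order; floats keep full precision.
#'
#' @param table Single-cell tibble.
#' @param path Output CSV path.
#' @param markers Marker column order; defaults to [marker_columns()] of
#'   `table`.
#' @return `path`, invisibly.
#' @export
write_single_cell_table <- function(table, path, markers = NULL) {
  if (is.null(markers)) markers <- marker_columns(table)
  required <- c("cell_id", "case_id", "x_um", "y_um", "area_um2")
  missing <- setdiff(c(required, markers), names(table))
  if (length(missing) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- table[, c(required, markers)]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a single-cell table from CSV
#'
#' @param path CSV path.
#' @param panel Optional [marker_panel()]; when given, every panel marker
#'   must be present as a column.
#' @param markers Optional explicit marker list (overrides `panel`).
#' @return A single-cell tibble.
#' @export
read_single_cell_table <- function(path, panel = NULL, markers = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cell_id", "case_id", "x_um", "y_um", "area_um2")
  if (is.null(markers) && !is.null(panel)) markers <- panel$markers
  for (col in c(required, markers)) {
    if (!col %in% names(tbl)) {
      stop(sprintf("single-cell table schema error: missing column '%s'",
                   col), call. = FALSE)
    }
  }
  tbl$cell_id <- as.integer(tbl$cell_id)
  tbl$case_id <- as.character(tbl$case_id)
  validate_cell_table(tbl)
  tbl
}

#' Validate single-cell table invariants
#'
#' Checks that `cell_id` is unique within each case, areas are positive and
#' marker intensities are non-negative.
#'
#' @param table Single-cell tibble.
#' @param markers Marker columns to check; defaults to [marker_columns()].
#' @return `table`, invisibly.
#' @export
validate_cell_table <- function(table, markers = NULL) {
  if (is.null(markers)) markers <- marker_columns(table)
  if (nrow(table) > 0) {
    dup <- duplicated(table[, c("case_id", "cell_id")])
    if (any(dup)) stop("cell_id not unique within case", call. = FALSE)
    if (any(table$area_um2 <= 0)) {
      stop("area_um2 must be positive", call. = FALSE)
    }
    for (m in markers) {
      if (any(table[[m]] < 0, na.rm = TRUE)) {
        stop(sprintf("marker '%s' has negative intensities", m),
             call. = FALSE)
      }
    }
  }
  invisible(table)
}
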