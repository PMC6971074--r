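#' Construct a marker panel
#'
#' A marker panel describes the channel layout of a cyclic
#' immunofluorescence experiment: the ordered marker names of the aligned
#' stack, the physical pixel size, and which markers were acquired in which
#' staining round. Every round carries its own DAPI counterstain, used for
#' registration; the aligned stack keeps a single DAPI channel.
#'
#' @param markers Character vector of unique marker names for the aligned
#'   stack, including `"DAPI"`.
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param round_markers List of character vectors, one per staining round,
#'   each naming that round's channels in order and containing `"DAPI"`
#'   exactly once. Defaults to a single round holding all `markers`.
#' @return An object of class `marker_panel`.
#' @export
#' @examples
#' marker_panel(c("DAPI", "CD3", "CD8"), pixel_size_um = 0.5)
marker_panel <- function(markers, pixel_size_um,
                         round_markers = list(markers)) {
  markers <- as.character(markers)
  if (anyDuplicated(markers) > 0) {
    stop("marker names must be unique", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  if (!"DAPI" %in% markers) {
    stop("panel must contain a 'DAPI' channel", call. = FALSE)
  }
  round_markers <- lapply(round_markers, as.character)
  for (r in seq_along(round_markers)) {
    if (sum(round_markers[[r]] == "DAPI") != 1) {
      stop(sprintf("round %d must contain exactly one DAPI channel", r),
           call. = FALSE)
    }
  }
  non_dapi <- unlist(lapply(round_markers, setdiff, "DAPI"))
  if (anyDuplicated(non_dapi) > 0) {
    stop("a non-DAPI marker appears in more than one round", call. = FALSE)
  }
  if (!setequal(c("DAPI", non_dapi), markers)) {
    stop("round markers do not cover the panel marker list", call. = FALSE)
  }
  structure(
    list(markers = markers,
         pixel_size_um = pixel_size_um,
         rounds = length(round_markers),
         round_markers = round_markers),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d markers, %d round(s), %.3g um/px\n",
              length(x$markers), x$rounds, x$pixel_size_um))
  cat("  ", paste(x$markers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Index of the DAPI channel within each round
#' @param panel A [marker_panel()].
#' @return Integer vector, one entry per round.
#' @export
dapi_channel_per_round <- function(panel) {
  vapply(panel$round_markers, function(m) which(m == "DAPI"), integer(1))
}

#' Read or write a marker panel as YAML
#'
#' @param path File path.
#' @return `read_panel()` returns a [marker_panel()]; `write_panel()`
#'   returns `path` invisibly.
#' @export
read_panel <- function(path) {
  y <- yaml::read_yaml(path)
  marker_panel(y$markers, y$pixel_size_um,
               round_markers = if (is.null(y$round_markers)) list(y$markers)
                               else y$round_markers)
}

#' @rdname read_panel
#' @param panel A [marker_panel()].
#' @export
write_panel <- function(panel, path) {
  yaml::write_yaml(list(markers = panel$markers,
                        pixel_size_um = panel$pixel_size_um,
                        round_markers = panel$round_markers), path)
  invisible(path)
}

# Columns of a single-cell table that are never marker measurements.
RESERVED_CELL_COLUMNS <- c("cell_id", "case_id", "x_um", "y_um", "area_um2",
                           "cluster_id", "cell_type", "true_type")

#' Marker columns of a single-cell table
#'
#' Returns the marker measurement columns of a per-cell table, i.e. every
#' column that is not one of the reserved bookkeeping columns
#' (`cell_id`, `case_id`, `x_um`, `y_um`, `area_um2`, `cluster_id`,
#' `cell_type`, `true_type`).
#'
#' @param table A single-cell tibble.
#' @return Character vector of marker column names.
#' @export
marker_columns <- function(table) {
  setdiff(names(table), RESERVED_CELL_COLUMNS)
}
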