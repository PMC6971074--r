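#' Quantify per-cell marker intensities and morphology
#'
#' For each labelled object, computes the mean intensity of every channel
#' over the object's pixels, the unweighted centroid and the pixel area,
#' converted to physical units via the panel's pixel size. Rows are ordered
#' by ascending label.
#'
#' @param image A [multiplex_image()] aligned with the mask.
#' @param mask A [label_mask()] of the same spatial shape.
#' @param case_id Case identifier stored in the table.
#' @return A single-cell tibble: `cell_id`, `case_id`, `x_um`, `y_um`,
#'   `area_um2`, one column per marker.
#' @export
quantify <- function(image, mask, case_id = "case") {
  d <- dim(image$channels)
  if (!all(d[1:2] == dim(mask$labels))) {
    stop("image and mask differ in spatial shape", call. = FALSE)
  }
  px <- image$panel$pixel_size_um
  markers <- image$panel$markers
  k <- n_labels(mask)
  if (k == 0) {
    out <- tibble::tibble(cell_id = integer(0), case_id = character(0),
                          x_um = numeric(0), y_um = numeric(0),
                          area_um2 = numeric(0))
    for (m in markers) out[[m]] <- numeric(0)
    return(out)
  }
  idx <- which(mask$labels > 0)
  lv <- mask$labels[idx]
  ny <- d[1]
  ys <- (idx - 1) %% ny        # 0-based row (y)
  xs <- (idx - 1) %/% ny       # 0-based column (x)
  cnt <- tabulate(lv, nbins = k)
  cx <- unname(rowsum(xs, lv)[, 1]) / cnt
  cy <- unname(rowsum(ys, lv)[, 1]) / cnt
  out <- tibble::tibble(cell_id = seq_len(k),
                        case_id = case_id,
                        x_um = cx * px, y_um = cy * px,
                        area_um2 = cnt * px^2)
  for (j in seq_along(markers)) {
    ch <- image$channels[, , j]
    out[[markers[j]]] <- unname(rowsum(ch[idx], lv)[, 1]) / cnt
  }
  out
}

#' Cell density per square millimetre
#'
#' @param table Single-cell tibble.
#' @param area_mm2 Analyzed tissue area in square millimetres (> 0).
#' @return Cells per square millimetre.
#' @export
#' @examples
#' cell_density(tibble::tibble(cell_id = 1:628), area_mm2 = 6.28)
cell_density <- function(table, area_mm2) {
  if (!is.numeric(area_mm2) || length(area_mm2) != 1 || area_mm2 <= 0) {
    stop("`area_mm2` must be a single positive number", call. = FALSE)
  }
  nrow(table) / area_mm2
}
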