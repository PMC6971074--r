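#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold_value Intensity threshold when
#'   `threshold_method = "fixed"`.
#' @param min_area_um2 Minimum object area kept, square micrometres.
#' @param smoothing_sigma_um Gaussian smoothing sigma before thresholding,
#'   micrometres (0 disables smoothing).
#' @param combine_method How lineage channels are combined for the
#'   targeted mask: pixelwise `"max"` (default) or `"sum"` of
#'   percentile-normalized channels.
#' @param min_solidity Minimum solidity for [exclude_fragments()].
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                threshold_value = NULL,
                                min_area_um2 = 12,
                                smoothing_sigma_um = 1,
                                combine_method = c("max", "sum"),
                                min_solidity = 0.5) {
  threshold_method <- match.arg(threshold_method)
  combine_method <- match.arg(combine_method)
  if (threshold_method == "fixed" && is.null(threshold_value)) {
    stop("`threshold_value` required for fixed thresholding", call. = FALSE)
  }
  stopifnot(min_area_um2 > 0, smoothing_sigma_um >= 0,
            min_solidity >= 0, min_solidity <= 1)
  structure(list(threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_area_um2 = min_area_um2,
                 smoothing_sigma_um = smoothing_sigma_um,
                 combine_method = combine_method,
                 min_solidity = min_solidity),
            class = "segmentation_params")
}

smooth_channel <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  # replicate boundary: circular filtering would wrap one image edge into
  # the opposite one and bridge objects across the border
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma_px,
                           boundary = "replicate"))
}

threshold_image <- function(m, params) {
  if (params$threshold_method == "fixed") {
    return(m > params$threshold_value)
  }
  hi <- max(m)
  if (hi <= 0) return(matrix(FALSE, nrow(m), ncol(m)))
  th <- EBImage::otsu(EBImage::Image(m / hi), range = c(0, 1)) * hi
  m > th
}

# Drop labels below a minimum pixel count; relabel consecutively.
filter_small <- function(labels, min_px) {
  if (max(labels) == 0) return(labels)
  cnt <- tabulate(labels[labels > 0])
  keep <- which(cnt >= min_px)
  map <- integer(length(cnt))
  map[keep] <- seq_along(keep)
  out <- labels
  out[out > 0] <- map[out[out > 0]]
  out
}

#' Build the DAPI nuclear mask
#'
#' Gaussian-smooths the DAPI channel, thresholds it (Otsu by default),
#' labels 8-connected components and drops objects smaller than
#' `min_area_um2`.
#'
#' @param image A [multiplex_image()] with a DAPI channel.
#' @param params A [segmentation_params()].
#' @return A [label_mask()] of kind `"nuclear"`.
#' @export
make_nuclear_mask <- function(image, params = segmentation_params()) {
  dapi <- get_channel(image, "DAPI")
  if (stats::sd(dapi) == 0) {
    stop("degenerate image: DAPI channel is constant", call. = FALSE)
  }
  px <- image$panel$pixel_size_um
  sm <- smooth_channel(dapi, params$smoothing_sigma_um / px)
  lab <- label_components(threshold_image(sm, params))
  lab <- filter_small(lab, params$min_area_um2 / px^2)
  label_mask(lab, kind = "nuclear", pixel_size_um = px)
}

#' Build the combined-lineage "targeted" mask
#'
#' Segments cells from leukocyte lineage channels instead of nuclei:
#' each lineage channel is rescaled to \[0, 1\] by its 99.9th percentile,
#' the channels are combined pixelwise (max by default), and the combined
#' image is smoothed, thresholded, labelled (8-connected) and cleaned with
#' [exclude_fragments()]. This mask captures dim-DAPI macrophages that a
#' nuclear threshold misses.
#'
#' @param image A [multiplex_image()].
#' @param lineage_markers Channels to combine; defaults to the subset of
#'   CD43, CD45, CD68, CD163 present in the panel.
#' @param params A [segmentation_params()].
#' @return A [label_mask()] of kind `"targeted"`.
#' @export
make_targeted_mask <- function(image, lineage_markers = NULL,
                               params = segmentation_params()) {
  if (is.null(lineage_markers)) {
    lineage_markers <- intersect(c("CD43", "CD45", "CD68", "CD163"),
                                 image$panel$markers)
  }
  if (length(lineage_markers) == 0) {
    stop("`lineage_markers` must name at least one channel", call. = FALSE)
  }
  missing <- setdiff(lineage_markers, image$panel$markers)
  if (length(missing) > 0) {
    stop(sprintf("lineage marker(s) not in panel: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  px <- image$panel$pixel_size_um
  d <- dim(image$channels)[1:2]
  combined <- matrix(0, d[1], d[2])
  for (m in lineage_markers) {
    ch <- image$channels[, , m]
    q <- stats::quantile(ch, 0.999, names = FALSE)
    if (q <= 0) next
    norm <- pmin(ch / q, 1)
    combined <- if (params$combine_method == "max") pmax(combined, norm)
                else combined + norm
  }
  sm <- smooth_channel(combined, params$smoothing_sigma_um / px)
  lab <- label_components(threshold_image(sm, params))
  lab <- filter_small(lab, params$min_area_um2 / px^2)
  mask <- label_mask(lab, kind = "targeted", pixel_size_um = px)
  exclude_fragments(mask, min_area_um2 = params$min_area_um2,
                    min_solidity = params$min_solidity)
}

#' Digitally exclude small or dendritic fragments
#'
#' Removes labelled objects with area below `min_area_um2` or solidity
#' (pixel area over convex-hull area) below `min_solidity`, mimicking the
#' digital exclusion of small dendritic-shaped cytoplasm fragments from a
#' lineage-based mask, then relabels consecutively from 1. Idempotent.
#'
#' @param mask A [label_mask()].
#' @param min_area_um2 Minimum area kept, square micrometres.
#' @param min_solidity Minimum solidity kept, in \[0, 1\].
#' @return A filtered [label_mask()].
#' @export
exclude_fragments <- function(mask, min_area_um2 = 12, min_solidity = 0.5) {
  labels <- mask$labels
  k <- max(labels)
  if (k == 0) return(mask)
  px <- mask$pixel_size_um
  idx <- which(labels > 0)
  lv <- labels[idx]
  ny <- nrow(labels)
  ys <- (idx - 1) %% ny
  xs <- (idx - 1) %/% ny
  cnt <- tabulate(lv, nbins = k)
  keep <- logical(k)
  by_label_y <- split(ys, lv)
  by_label_x <- split(xs, lv)
  for (l in seq_len(k)) {
    area_um2 <- cnt[l] * px^2
    if (area_um2 < min_area_um2) next
    keep[l] <- object_solidity(by_label_x[[as.character(l)]],
                               by_label_y[[as.character(l)]]) >= min_solidity
  }
  map <- integer(k)
  map[keep] <- seq_len(sum(keep))
  out <- labels
  out[out > 0] <- map[out[out > 0]]
  label_mask(out, kind = mask$kind, pixel_size_um = px)
}

# Solidity: pixel count over convex-hull area of the pixel centres
# (shoelace), capped at 1; degenerate hulls count as solid.
object_solidity <- function(xs, ys) {
  n <- length(xs)
  if (n <= 3) return(1)
  pts <- cbind(xs, ys)
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  m <- length(h)
  if (m < 3) return(1)
  area <- abs(sum(hx * hy[c(2:m, 1)] - hx[c(2:m, 1)] * hy)) / 2
  if (area <= 0) return(1)
  min(1, n / area)
}

#' Nuclear-over-targeted mask yield ratio
#'
#' The ratio of object counts in the nuclear (DAPI) mask over the targeted
#' (lineage) mask of the same field. Values below 1 reflect cells (chiefly
#' dim-DAPI macrophages) visible to the lineage channels but missed by
#' DAPI thresholding.
#'
#' @param nuclear,targeted [label_mask()]s of the same shape.
#' @return A single ratio; `NaN` when the targeted mask is empty.
#' @export
compare_mask_yield <- function(nuclear, targeted) {
  if (!all(dim(nuclear$labels) == dim(targeted$labels))) {
    stop("masks differ in shape", call. = FALSE)
  }
  nt <- n_labels(targeted)
  if (nt == 0) return(NaN)
  n_labels(nuclear) / nt
}
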