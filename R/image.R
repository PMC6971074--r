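#' Multiplex image stacks
#'
#' A `multiplex_image` bundles a stack of co-registered fluorescence
#' channels with its panel metadata. Channels are stored as a numeric array
#' of dimension `(ny, nx, n_markers)`; intensities are non-negative, in
#' arbitrary fluorescence units on a 16-bit scale (0--65535). Pixel indices
#' are 0-based and y-down; physical coordinates in micrometres are
#' `index * pixel_size_um`.
#'
#' @param channels Numeric array `(ny, nx, n_markers)`, all values >= 0.
#' @param panel A [marker_panel()] whose markers match the third dimension.
#' @return An object of class `multiplex_image`.
#' @export
multiplex_image <- function(channels, panel) {
  if (length(dim(channels)) == 2) {
    channels <- array(channels, c(dim(channels), 1L))
  }
  stopifnot(length(dim(channels)) == 3)
  if (dim(channels)[3] != length(panel$markers)) {
    stop(sprintf("channel count (%d) does not match panel marker count (%d)",
                 dim(channels)[3], length(panel$markers)), call. = FALSE)
  }
  if (any(channels < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  dimnames(channels) <- list(NULL, NULL, panel$markers)
  structure(list(channels = channels, panel = panel),
            class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<multiplex_image> %d x %d px, %d channels, %.3g um/px\n",
              d[1], d[2], d[3], x$panel$pixel_size_um))
  invisible(x)
}

#' Extract a single channel as a matrix
#' @param image A [multiplex_image()].
#' @param marker Marker name.
#' @return Numeric matrix `(ny, nx)`.
#' @export
get_channel <- function(image, marker) {
  if (!marker %in% image$panel$markers) {
    stop(sprintf("marker '%s' not in panel", marker), call. = FALSE)
  }
  image$channels[, , marker]
}

#' Read a multi-page TIFF as a multiplex image
#'
#' One TIFF page per marker, ordered as in the panel. Unsigned 8/16-bit and
#' float pages are accepted; values are rescaled back to the package's
#' native 16-bit intensity scale.
#'
#' @param path Path to a multi-page TIFF.
#' @param panel A [marker_panel()]; page count must equal its marker count.
#' @return A [multiplex_image()].
#' @export
read_multiplex_image <- function(path, panel) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e) {
                      stop(sprintf("cannot read TIFF '%s': %s",
                                   path, conditionMessage(e)), call. = FALSE)
                    })
  if (length(pages) != length(panel$markers)) {
    stop(sprintf(
      "TIFF page count mismatch: expected %d (panel), found %d in '%s'",
      length(panel$markers), length(pages), path), call. = FALSE)
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(ny, nx, length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (!all(dim(p) == c(ny, nx))) {
      stop("TIFF pages differ in spatial dimensions", call. = FALSE)
    }
    # readTIFF scales integer data to [0,1]; restore the 16-bit scale
    arr[, , i] <- round(p * 65535)
  }
  multiplex_image(arr, panel)
}

#' Write a multiplex image as a multi-page TIFF
#'
#' Channels are written as 16-bit pages; intensities are clipped to
#' `[0, 65535]` and rounded, so integer-valued stacks round-trip bitwise.
#'
#' @param image A [multiplex_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multiplex_image <- function(image, path) {
  pages <- lapply(seq_len(dim(image$channels)[3]), function(i) {
    pmin(pmax(image$channels[, , i], 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Label masks
#'
#' An integer-labelled segmentation image: 0 is background and the positive
#' labels are consecutive `1..K`, each one 8-connected component.
#'
#' @param labels Integer matrix of non-negative labels.
#' @param kind `"nuclear"` (DAPI mask) or `"targeted"` (combined
#'   leukocyte-lineage mask).
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, kind = c("nuclear", "targeted"),
                       pixel_size_um) {
  kind <- match.arg(kind)
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  u <- sort(unique(labels[labels > 0]))
  if (length(u) > 0 && !identical(u, seq_along(u))) {
    stop("positive labels must be consecutive 1..K", call. = FALSE)
  }
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0)
  structure(list(labels = labels, kind = kind,
                 pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask:%s> %d x %d px, %d objects\n", x$kind,
              nrow(x$labels), ncol(x$labels), n_labels(x)))
  invisible(x)
}

#' Number of labelled objects in a mask
#' @param mask A [label_mask()].
#' @return Integer count of positive labels.
#' @export
n_labels <- function(mask) {
  max(0L, max(mask$labels))
}

#' Label connected components of a binary image
#'
#' 8-connected labelling: 4-connected components are found first and label
#' pairs that touch diagonally are then merged, so objects joined only
#' through a diagonal pixel count as one.
#'
#' @param binary Logical or 0/1 numeric matrix.
#' @return Integer matrix of consecutive labels, 0 = background.
#' @export
label_components <- function(binary) {
  b <- matrix(as.numeric(binary > 0), nrow(binary), ncol(binary))
  lab4 <- EBImage::bwlabel(b)
  lab4 <- matrix(as.integer(lab4), nrow(b), ncol(b))
  k <- max(lab4)
  if (k <= 1) return(lab4)
  ny <- nrow(lab4); nx <- ncol(lab4)
  # diagonal label adjacencies
  d1a <- lab4[-ny, -nx]; d1b <- lab4[-1, -1]     # down-right
  d2a <- lab4[-ny, -1];  d2b <- lab4[-1, -nx]    # down-left
  keep1 <- d1a > 0 & d1b > 0 & d1a != d1b
  keep2 <- d2a > 0 & d2b > 0 & d2a != d2b
  pairs <- rbind(cbind(d1a[keep1], d1b[keep1]),
                 cbind(d2a[keep2], d2b[keep2]))
  if (nrow(pairs) == 0) return(lab4)
  g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, k - igraph::vcount(g)))
  comp <- as.integer(igraph::components(g)$membership)
  out <- lab4
  out[out > 0] <- comp[out[out > 0]]
  # relabel consecutively 1..K
  u <- sort(unique(out[out > 0]))
  out[out > 0] <- match(out[out > 0], u)
  out
}

#' Read/write a label mask as 16-bit TIFF
#' @param path File path.
#' @inheritParams label_mask
#' @return `read_label_mask()` returns a [label_mask()].
#' @export
write_label_mask <- function(mask, path) {
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_mask
#' @param mask A [label_mask()].
#' @export
read_label_mask <- function(path, kind = c("nuclear", "targeted"),
                            pixel_size_um) {
  m <- tiff::readTIFF(path)
  label_mask(round(m * 65535), kind = match.arg(kind),
             pixel_size_um = pixel_size_um)
}
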