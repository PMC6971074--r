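#' Register staining rounds on their DAPI channels
#'
#' Cyclic staining re-acquires the same section once per round; rounds are
#' aligned by estimating the integer-pixel rigid translation of each
#' round's DAPI channel against the first round, via FFT cross-correlation
#' of the mean-centred images. The inverse shift is applied to every
#' channel of the round (out-of-frame pixels zero-filled) and the aligned
#' non-DAPI channels are concatenated with the round-1 DAPI into a single
#' stack.
#'
#' @param rounds List of [multiplex_image()], one per round, each
#'   containing a DAPI channel.
#' @return A list with `image` (aligned [multiplex_image()]) and
#'   `registration` (tibble of `round`, `dy`, `dx`, `peak_correlation`).
#' @export
register_rounds <- function(rounds) {
  if (length(rounds) == 0) {
    stop("`rounds` must contain at least one image", call. = FALSE)
  }
  dapis <- lapply(rounds, get_channel, "DAPI")
  for (r in seq_along(dapis)) {
    if (stats::sd(dapis[[r]]) == 0) {
      stop(sprintf("degenerate image: round %d DAPI has zero variance", r),
           call. = FALSE)
    }
  }
  ref <- dapis[[1]]
  reg <- tibble::tibble(round = seq_along(rounds), dy = 0L, dx = 0L,
                        peak_correlation = 1)
  aligned <- vector("list", length(rounds))
  aligned[[1]] <- rounds[[1]]
  for (r in seq_along(rounds)[-1]) {
    sh <- estimate_shift(ref, dapis[[r]])
    reg$dy[r] <- sh[1]; reg$dx[r] <- sh[2]
    ch <- rounds[[r]]$channels
    out <- ch
    for (k in seq_len(dim(ch)[3])) {
      out[, , k] <- shift_matrix(ch[, , k], -sh[1], -sh[2])
    }
    aligned[[r]] <- multiplex_image(out, rounds[[r]]$panel)
    reg$peak_correlation[r] <-
      overlap_correlation(ref, aligned[[r]]$channels[, , "DAPI"], sh)
  }
  markers <- "DAPI"
  ny <- nrow(ref); nx <- ncol(ref)
  stacks <- list(rounds[[1]]$channels[, , "DAPI"])
  for (r in seq_along(rounds)) {
    for (m in setdiff(rounds[[r]]$panel$markers, "DAPI")) {
      markers <- c(markers, m)
      stacks <- c(stacks, list(aligned[[r]]$channels[, , m]))
    }
  }
  arr <- array(unlist(stacks), c(ny, nx, length(markers)))
  # a marker re-acquired in several rounds keeps one channel per round
  panel <- marker_panel(make.unique(markers),
                        rounds[[1]]$panel$pixel_size_um)
  list(image = multiplex_image(arr, panel), registration = reg)
}

# Estimate integer translation (dy, dx) such that moving == shift of ref
# by (dy, dx); FFT cross-correlation of mean-centred images.
estimate_shift <- function(ref, moving) {
  a <- ref - mean(ref); b <- moving - mean(moving)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  pk <- which.max(cc)
  ny <- nrow(a); nx <- ncol(a)
  dy <- (pk - 1) %% ny
  dx <- (pk - 1) %/% ny
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(as.integer(dy), as.integer(dx))
}

# Pearson correlation of the region where both images are valid after a
# shift of (dy, dx).
overlap_correlation <- function(ref, aligned, sh) {
  ny <- nrow(ref); nx <- ncol(ref)
  ys <- max(1, 1 - sh[1]):min(ny, ny - sh[1])
  xs <- max(1, 1 - sh[2]):min(nx, nx - sh[2])
  a <- ref[ys, xs]; b <- aligned[ys, xs]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(as.vector(a), as.vector(b))
}

#' Subtract an autofluorescence reference channel
#'
#' Every non-DAPI channel becomes `max(0, channel - scale * af)`, where
#' `af` is a blank reference channel capturing tissue autofluorescence; the
#' reference channel itself is removed from the output panel. DAPI is left
#' untouched. Subtraction never produces negative intensities and is
#' pixelwise monotone non-increasing in `scale`.
#'
#' @param image A [multiplex_image()].
#' @param af_channel Name of the autofluorescence channel (default
#'   `"AF"`).
#' @param scale Non-negative global scale factor (default 1).
#' @return A [multiplex_image()] without the autofluorescence channel.
#' @export
subtract_autofluorescence <- function(image, af_channel = "AF", scale = 1) {
  stopifnot(scale >= 0)
  if (!af_channel %in% image$panel$markers) {
    stop(sprintf("autofluorescence channel '%s' not in panel", af_channel),
         call. = FALSE)
  }
  af <- image$channels[, , af_channel]
  keep <- setdiff(image$panel$markers, af_channel)
  arr <- array(0, c(dim(af), length(keep)))
  for (k in seq_along(keep)) {
    ch <- image$channels[, , keep[k]]
    if (keep[k] != "DAPI") ch <- pmax(ch - scale * af, 0)
    arr[, , k] <- ch
  }
  rm_af <- function(v) setdiff(v, af_channel)
  panel <- marker_panel(keep, image$panel$pixel_size_um,
                        round_markers = {
                          rms <- lapply(image$panel$round_markers, rm_af)
                          rms[vapply(rms, length, 1L) > 0]
                        })
  multiplex_image(arr, panel)
}
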