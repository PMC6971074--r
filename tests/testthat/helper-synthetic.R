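# Shared fixture builders for the test suite; everything is generated in
# code at test time.

# A phenotype with the given high markers on the default panel profile.
mk_phenotype <- function(name, high, dapi_factor = 1, abundance = 1,
                         radius_um = 5, mid = NULL) {
  pr <- mxifcell:::syn_profile(high, mid)
  phenotype_spec(name, pr$means, pr$sds,
                 dapi_intensity_factor = dapi_factor,
                 radius_um = radius_um, abundance = abundance)
}

# Small single-round panel for fast imaging tests.
mini_panel <- function(markers = c("DAPI", "CD3"), pixel_size_um = 0.5) {
  marker_panel(markers, pixel_size_um)
}

# Deterministic multiplex image with uniform disks at given centres (px).
disk_image <- function(panel, ny, nx, disks) {
  arr <- array(0, c(ny, nx, length(panel$markers)))
  for (d in disks) {
    yy <- outer(seq_len(ny) - 1 - d$cy, rep(1, nx))
    xx <- outer(rep(1, ny), seq_len(nx) - 1 - d$cx)
    m <- yy^2 + xx^2 <= d$r^2
    ch <- match(d$marker, panel$markers)
    plane <- arr[, , ch]
    plane[m] <- d$value
    arr[, , ch] <- plane
  }
  multiplex_image(arr, panel)
}

# Renders a tissue and returns the autofluorescence-subtracted aligned
# image (the standard front half of the pipeline).
render_aligned <- function(spec, seed) {
  sim <- generate_cell_table(spec, seed = seed)
  rounds <- render_image(sim$cells, spec, seed = seed + 10000L)
  img <- register_rounds(rounds)$image
  list(image = subtract_autofluorescence(img, "AF"), sim = sim)
}

# Clark-Evans nearest-neighbour index for a point set in a rectangle.
clark_evans <- function(cells, field_um) {
  D <- as.matrix(stats::dist(cbind(cells$x_um, cells$y_um)))
  diag(D) <- Inf
  mean(apply(D, 1, min)) /
    (0.5 / sqrt(nrow(cells) / prod(field_um)))
}

# Exclusive A-B pairs 10 um apart, the constructed short-range
# co-occurrence pattern.
pair_pattern <- function(n_pairs, field = 3000, gap_um = 10, seed = 1) {
  set.seed(seed)
  bx <- stats::runif(n_pairs, 50, field - 50)
  by <- stats::runif(n_pairs, 50, field - 50)
  th <- stats::runif(n_pairs, 0, 2 * pi)
  tibble::tibble(
    x_um = c(bx, bx + gap_um * cos(th)),
    y_um = c(by, by + gap_um * sin(th)),
    cell_type = rep(c("B", "A"), each = n_pairs))
}
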