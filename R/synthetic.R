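#' Phenotype specification for synthetic tissue
#'
#' Describes one cell type of a simulated tissue: its mean and sd of
#' expression per marker (arbitrary fluorescence units), the factor applied
#' to its DAPI signal (macrophage-like types use values < 1, mimicking
#' their reduced chromatin DAPI staining), its disk radius and its
#' abundance within the tissue.
#'
#' @param name Cell-type name.
#' @param marker_means Named numeric vector, mean expression per marker.
#' @param marker_sds Named numeric vector (>= 0), sd per marker; markers
#'   absent here default to sd 0.
#' @param dapi_intensity_factor Multiplier in (0, 1] applied to the DAPI
#'   mean of this type.
#' @param radius_um Cell radius in micrometres.
#' @param abundance Proportion of cells of this type, in (0, 1).
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name, marker_means, marker_sds = NULL,
                           dapi_intensity_factor = 1, radius_um = 4,
                           abundance = 1) {
  if (is.null(marker_sds)) {
    marker_sds <- stats::setNames(rep(0, length(marker_means)),
                                  names(marker_means))
  }
  stopifnot(all(marker_sds >= 0),
            dapi_intensity_factor > 0, dapi_intensity_factor <= 1,
            radius_um > 0, abundance > 0, abundance <= 1)
  structure(list(name = name,
                 marker_means = marker_means,
                 marker_sds = marker_sds,
                 dapi_intensity_factor = dapi_intensity_factor,
                 radius_um = radius_um,
                 abundance = abundance),
            class = "phenotype_spec")
}

#' Tissue specification for synthetic image generation
#'
#' @param phenotypes List of [phenotype_spec()]; abundances must sum to 1.
#' @param n_cells Number of cells to draw.
#' @param field_um Numeric `(width, height)` of the field, micrometres.
#' @param panel [marker_panel()] used for rendering; defaults to
#'   [default_panel()].
#' @param spatial_model A list: `list(model = "csr")` (complete spatial
#'   randomness), `list(model = "clustered", type =, parent_rate =,
#'   cluster_sd =)` (Thomas-style parent/offspring clustering of one type;
#'   `parent_rate` in parents per square millimetre, `cluster_sd` in
#'   micrometres), or `list(model = "avoidance", type_a =, type_b =,
#'   min_dist_um =)` (hard-core inhibition between two types).
#' @param af_level Mean autofluorescence background added to every channel.
#' @param shift_per_round List of integer `(dy, dx)` pixel offsets, one per
#'   panel round; defaults to all zero.
#' @param noise_sd Gaussian pixel noise sd (truncated at zero).
#' @param min_dist_um Minimum centre-to-centre distance between any two
#'   cells (rejection sampling); 0 disables the hard core.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(phenotypes, n_cells, field_um = c(400, 400),
                        panel = default_panel(),
                        spatial_model = list(model = "csr"),
                        af_level = 3, shift_per_round = NULL,
                        noise_sd = 2, min_dist_um = 0) {
  stopifnot(n_cells >= 1, length(field_um) == 2, all(field_um > 0),
            af_level >= 0, noise_sd >= 0, min_dist_um >= 0)
  ab <- vapply(phenotypes, `[[`, numeric(1), "abundance")
  if (abs(sum(ab) - 1) > 1e-9) {
    stop(sprintf("phenotype abundances must sum to 1 (got %.6f)", sum(ab)),
         call. = FALSE)
  }
  if (is.null(shift_per_round)) {
    shift_per_round <- rep(list(c(0L, 0L)), panel$rounds)
  }
  stopifnot(length(shift_per_round) == panel$rounds)
  structure(list(phenotypes = phenotypes, n_cells = as.integer(n_cells),
                 field_um = field_um, panel = panel,
                 spatial_model = spatial_model, af_level = af_level,
                 shift_per_round = shift_per_round, noise_sd = noise_sd,
                 min_dist_um = min_dist_um),
            class = "tissue_spec")
}

#' Default 18-channel marker panel for simulation
#'
#' DAPI, a blank autofluorescence reference channel (`AF`) and 16 immune
#' markers spread over four staining rounds (each round re-acquires DAPI),
#' covering every default cell-type rule: pan-leukocyte and lineage
#' markers (CD43, CD45, CD3, CD4, CD8, CD20, CD16, CD68, CD163) and
#' function markers (FOXP3, TCF7, PD1, GranzymeB, Granulysin, LYZ,
#' VISTA). Both pan-leukocyte channels (CD43, CD45) are kept so the
#' combined targeted mask never hinges on a single channel's noise.
#'
#' @param pixel_size_um Pixel size, micrometres (default 0.5).
#' @return A [marker_panel()].
#' @export
default_panel <- function(pixel_size_um = 0.5) {
  marker_panel(
    markers = c("DAPI", "AF", "CD43", "CD45", "CD3", "CD4", "CD8", "CD20",
                "FOXP3", "TCF7", "PD1", "GranzymeB", "Granulysin", "CD16",
                "CD68", "CD163", "LYZ", "VISTA"),
    pixel_size_um = pixel_size_um,
    round_markers = list(
      c("DAPI", "AF", "CD43", "CD45", "CD3", "CD4"),
      c("DAPI", "CD8", "CD20", "FOXP3", "TCF7"),
      c("DAPI", "PD1", "GranzymeB", "Granulysin", "CD16"),
      c("DAPI", "CD68", "CD163", "LYZ", "VISTA")))
}

# Intensity levels for the synthetic profiles (arbitrary units).
SYN_HI <- 100; SYN_LO <- 5; SYN_SD_HI <- 15; SYN_SD_LO <- 3
SYN_DAPI <- 200; SYN_SPOTTY <- 10; SYN_SD_SPOTTY <- 10

syn_profile <- function(high = character(), mid = NULL) {
  nm <- setdiff(default_panel()$markers, c("DAPI", "AF"))
  means <- stats::setNames(rep(SYN_LO, length(nm)), nm)
  sds <- stats::setNames(rep(SYN_SD_LO, length(nm)), nm)
  means[high] <- SYN_HI; sds[high] <- SYN_SD_HI
  if (!is.null(mid)) {
    means[names(mid)] <- unlist(mid)
    sds[names(mid)] <- pmax(SYN_SD_LO, unlist(mid) * 0.5)
  }
  means <- c(DAPI = SYN_DAPI, AF = 0, means)
  sds <- c(DAPI = 20, AF = 0, sds)
  list(means = means, sds = sds)
}

#' Default synthetic phenotype set
#'
#' Nine immune phenotypes (CD4 T, CD8 T, NK, B, TAM, histiocyte, phagocyte,
#' inflammatory monocyte, undefined monocyte/macrophage) with
#' repo-defined synthetic expression profiles, plus an optional
#' marker-negative tumour phenotype. The macrophage-lineage types carry
#' `dapi_intensity_factor < 1` so that a DAPI-threshold nuclear mask
#' under-detects them, as happens with real macrophages whose chromatin
#' DAPI staining is reduced. Immune abundances are proportions of the
#' immune compartment and are scaled by `1 - tumor_fraction`.
#'
#' @param tumor_fraction Fraction of cells that are marker-negative tumour
#'   cells (default 0.35; 0 yields the nine immune phenotypes only).
#' @return List of [phenotype_spec()].
#' @export
default_phenotypes <- function(tumor_fraction = 0.35) {
  stopifnot(tumor_fraction >= 0, tumor_fraction < 1)
  immune <- list(
    list("CD4_T", c("CD43", "CD45", "CD3", "CD4", "FOXP3"),
         NULL, 1.0, 4.0, 0.10),
    list("CD8_T", c("CD43", "CD45", "CD3", "CD8"),
         list(PD1 = 60, TCF7 = 40), 1.0, 4.0, 0.15),
    list("NK", c("CD43", "CD45", "GranzymeB", "Granulysin"),
         NULL, 1.0, 4.0, 0.05),
    list("B", c("CD43", "CD45", "CD20"), NULL, 1.0, 4.0, 0.05),
    list("TAM", c("CD43", "CD45", "CD16", "CD68", "CD163"),
         NULL, 0.35, 6.0, 0.25),
    list("Histiocyte", c("CD43", "CD45", "CD68", "CD163"),
         NULL, 0.60, 6.0, 0.15),
    list("Phagocyte", c("CD43", "CD45", "CD68"), NULL, 0.60, 6.0, 0.08),
    list("InflammatoryMonocyte", c("CD43", "CD45", "LYZ", "VISTA"),
         list(CD16 = 20), 1.0, 3.5, 0.07),
    list("MonoMac_undefined", c("CD43", "CD45"),
         list(LYZ = SYN_SPOTTY, CD68 = SYN_SPOTTY, CD163 = SYN_SPOTTY,
              VISTA = SYN_SPOTTY, CD16 = SYN_SPOTTY), 0.80, 5.0, 0.10))
  scale <- 1 - tumor_fraction
  specs <- lapply(immune, function(p) {
    pr <- syn_profile(p[[2]], p[[3]])
    phenotype_spec(p[[1]], pr$means, pr$sds,
                   dapi_intensity_factor = p[[4]], radius_um = p[[5]],
                   abundance = p[[6]] * scale)
  })
  if (tumor_fraction > 0) {
    pr <- syn_profile(character())
    specs <- c(specs, list(
      phenotype_spec("Tumor", pr$means, pr$sds, dapi_intensity_factor = 1,
                     radius_um = 5, abundance = tumor_fraction)))
  }
  specs
}

# Truncated-at-zero normal draws (exact truncation, not censoring).
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, lo, 1)
  pmin(stats::qnorm(u, mean, sd), mean + 8 * sd)
}

# Mean of a normal truncated at zero, for oracle checks.
truncnorm_mean <- function(mean, sd) {
  if (sd == 0) return(mean)
  a <- -mean / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# Sequentially place points with optional hard-core and pairwise
# type-avoidance constraints; grid-hashed neighbour lookup.
place_cells <- function(n, field, types, type_names, model, min_dist) {
  w <- field[1]; h <- field[2]
  x <- numeric(n); y <- numeric(n)
  avoid <- identical(model$model, "avoidance")
  pair_dist <- if (avoid) model$min_dist_um else 0
  check_r <- max(min_dist, pair_dist)
  use_grid <- check_r > 0
  if (use_grid) {
    cs <- check_r
    gnx <- max(1L, ceiling(w / cs)); gny <- max(1L, ceiling(h / cs))
    grid <- vector("list", gnx * gny)
    gidx <- function(px, py) {
      (pmin(gny - 1L, floor(py / cs))) * gnx + pmin(gnx - 1L, floor(px / cs)) + 1L
    }
  }
  clustered <- identical(model$model, "clustered")
  if (clustered) {
    area_mm2 <- w * h / 1e6
    n_par <- max(1L, stats::rpois(1, model$parent_rate * area_mm2))
    par_x <- stats::runif(n_par, 0, w); par_y <- stats::runif(n_par, 0, h)
  }
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(10000L)) {
      if (clustered && types[i] == model$type) {
        p <- sample.int(length(par_x), 1)
        cx <- stats::rnorm(1, par_x[p], model$cluster_sd)
        cy <- stats::rnorm(1, par_y[p], model$cluster_sd)
        if (cx < 0 || cx > w || cy < 0 || cy > h) next
      } else {
        cx <- stats::runif(1, 0, w); cy <- stats::runif(1, 0, h)
      }
      if (use_grid && i > 1) {
        gx <- min(gnx - 1L, floor(cx / cs)); gy <- min(gny - 1L, floor(cy / cs))
        nb <- integer(0)
        for (dy in -1:1) for (dx in -1:1) {
          ggx <- gx + dx; ggy <- gy + dy
          if (ggx < 0 || ggx >= gnx || ggy < 0 || ggy >= gny) next
          nb <- c(nb, grid[[ggy * gnx + ggx + 1L]])
        }
        if (length(nb) > 0) {
          d2 <- (x[nb] - cx)^2 + (y[nb] - cy)^2
          if (min_dist > 0 && any(d2 < min_dist^2)) next
          if (avoid) {
            ta <- model$type_a; tb <- model$type_b
            clash <- (types[i] == ta & types[nb] == tb) |
                     (types[i] == tb & types[nb] == ta)
            if (any(clash & d2 < pair_dist^2)) next
          }
        }
      }
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("placement error: could not place cell under spatial constraints",
           call. = FALSE)
    }
    x[i] <- cx; y[i] <- cy
    if (use_grid) {
      g <- gidx(cx, cy)
      grid[[g]] <- c(grid[[g]], i)
    }
  }
  cbind(x, y)
}

#' Generate a ground-truthed synthetic single-cell table
#'
#' Draws cell types from the phenotype abundances, places cells under the
#' spec's spatial model and samples each cell's expression per marker from
#' a zero-truncated normal with the phenotype's mean and sd. The DAPI mean
#' is scaled by the phenotype's `dapi_intensity_factor`. Identical
#' `(spec, seed)` give identical output.
#'
#' @param spec A [tissue_spec()].
#' @param seed Integer seed.
#' @return A list with `cells` (single-cell tibble; markers from the
#'   panel) and `truth` (tibble of `cell_id`, `true_type`, centre and true
#'   mean expression per marker).
#' @export
#' @examples
#' sim <- generate_cell_table(
#'   tissue_spec(default_phenotypes(), n_cells = 200), seed = 1)
#' dplyr::count(sim$truth, true_type)
generate_cell_table <- function(spec, seed) {
  stopifnot(inherits(spec, "tissue_spec"))
  set.seed(as.integer(seed))
  ph <- spec$phenotypes
  nm <- vapply(ph, `[[`, character(1), "name")
  ab <- vapply(ph, `[[`, numeric(1), "abundance")
  n <- spec$n_cells
  types <- nm[sample.int(length(nm), n, replace = TRUE, prob = ab)]
  pos <- place_cells(n, spec$field_um, types, nm, spec$spatial_model,
                     spec$min_dist_um)
  markers <- spec$panel$markers
  expr <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  true_mean <- expr
  for (j in seq_along(ph)) {
    idx <- which(types == nm[j])
    if (length(idx) == 0) next
    p <- ph[[j]]
    for (m in markers) {
      mu <- if (m %in% names(p$marker_means)) p$marker_means[[m]] else 0
      sdv <- if (m %in% names(p$marker_sds)) p$marker_sds[[m]] else 0
      if (m == "DAPI") mu <- mu * p$dapi_intensity_factor
      expr[idx, m] <- rtnorm0(length(idx), mu, sdv)
      true_mean[idx, m] <- mu
    }
  }
  radius <- vapply(ph, `[[`, numeric(1), "radius_um")[match(types, nm)]
  cells <- tibble::tibble(cell_id = seq_len(n), case_id = "synthetic",
                          x_um = pos[, 1], y_um = pos[, 2],
                          area_um2 = pi * radius^2)
  cells <- dplyr::bind_cols(cells, tibble::as_tibble(expr))
  truth <- tibble::tibble(cell_id = seq_len(n), true_type = types,
                          x_um = pos[, 1], y_um = pos[, 2],
                          radius_um = radius)
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(true_mean))
  list(cells = cells, truth = truth)
}

#' Render a synthetic cell table into per-round image stacks
#'
#' Each cell is drawn as a uniform disk of its phenotype radius carrying
#' its sampled expression value in every channel (DAPI already carries the
#' phenotype's DAPI attenuation from [generate_cell_table()]). Per round,
#' the scene is rigidly shifted by the spec's `(dy, dx)` pixel offset,
#' autofluorescence background `af_level` is added to every channel, and
#' zero-truncated Gaussian pixel noise of sd `noise_sd` is applied.
#'
#' @param cells Single-cell tibble from [generate_cell_table()].
#' @param spec The [tissue_spec()] used to generate it.
#' @param seed Integer seed (pixel noise).
#' @return List of [multiplex_image()], one per staining round.
#' @export
render_image <- function(cells, spec, seed) {
  set.seed(as.integer(seed))
  panel <- spec$panel
  px <- panel$pixel_size_um
  nx <- as.integer(round(spec$field_um[1] / px))
  ny <- as.integer(round(spec$field_um[2] / px))
  radius <- if ("radius_um" %in% names(cells)) cells$radius_um else
    sqrt(cells$area_um2 / pi)
  if (any(cells$x_um < 0 | cells$x_um > spec$field_um[1] |
          cells$y_um < 0 | cells$y_um > spec$field_um[2])) {
    stop("placement error: cell centre outside the field", call. = FALSE)
  }
  markers <- panel$markers
  scene <- array(0, c(ny, nx, length(markers)),
                 dimnames = list(NULL, NULL, markers))
  for (i in seq_len(nrow(cells))) {
    cxp <- cells$x_um[i] / px; cyp <- cells$y_um[i] / px
    rp <- radius[i] / px
    x0 <- max(0L, floor(cxp - rp)); x1 <- min(nx - 1L, ceiling(cxp + rp))
    y0 <- max(0L, floor(cyp - rp)); y1 <- min(ny - 1L, ceiling(cyp + rp))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    disk <- outer((ys - cyp)^2, (xs - cxp)^2, `+`) <= rp^2
    if (!any(disk)) next
    widx <- which(disk, arr.ind = TRUE)
    rows <- ys[widx[, 1]] + 1L; cols <- xs[widx[, 2]] + 1L
    for (m in markers) {
      v <- cells[[m]][i]
      if (v > 0) scene[cbind(rows, cols, match(m, markers))] <- v
    }
  }
  out <- vector("list", panel$rounds)
  for (r in seq_len(panel$rounds)) {
    ms <- panel$round_markers[[r]]
    sh <- spec$shift_per_round[[r]]
    stack <- array(0, c(ny, nx, length(ms)), dimnames = list(NULL, NULL, ms))
    for (k in seq_along(ms)) {
      ch <- shift_matrix(scene[, , ms[k]], sh[1], sh[2])
      ch <- ch + spec$af_level
      if (spec$noise_sd > 0) {
        ch <- ch + stats::rnorm(length(ch), 0, spec$noise_sd)
      }
      stack[, , k] <- pmax(ch, 0)
    }
    rp <- marker_panel(ms, px, round_markers = list(ms))
    out[[r]] <- multiplex_image(stack, rp)
  }
  out
}

# Integer-pixel rigid shift with zero fill: out[y, x] = m[y - dy, x - dx].
shift_matrix <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  okY <- ys >= 1 & ys <= ny; okX <- xs >= 1 & xs <= nx
  out[okY, okX] <- m[ys[okY], xs[okX]]
  out
}
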