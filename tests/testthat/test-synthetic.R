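test_that("cell-table generation is deterministic and validated", {
  ph <- list(mk_phenotype("A", "CD3", abundance = 0.5),
             mk_phenotype("B", "CD68", abundance = 0.5))
  spec <- tissue_spec(ph, n_cells = 100)
  s1 <- generate_cell_table(spec, seed = 1)
  s2 <- generate_cell_table(spec, seed = 1)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_cell_table(spec, seed = 2)
  expect_false(identical(s1$cells$x_um, s3$cells$x_um))

  bad <- list(mk_phenotype("A", "CD3", abundance = 0.5),
              mk_phenotype("B", "CD68", abundance = 0.6))
  expect_error(tissue_spec(bad, n_cells = 10), "sum to 1")
})

test_that("zero-sd phenotypes emit their means exactly", {
  pr <- mxifcell:::syn_profile("CD3")
  ph <- phenotype_spec("A", pr$means, NULL, radius_um = 4, abundance = 1)
  spec <- tissue_spec(list(ph), n_cells = 50)
  sim <- generate_cell_table(spec, seed = 7)
  expect_true(all(sim$cells$CD3 == pr$means[["CD3"]]))
  expect_true(all(sim$cells$CD68 == pr$means[["CD68"]]))
  expect_true(all(sim$cells$DAPI == pr$means[["DAPI"]]))
})

test_that("sampled type fractions match the multinomial abundances", {
  ph <- list(mk_phenotype("A", "CD3", abundance = 0.6),
             mk_phenotype("B", "CD68", abundance = 0.3),
             mk_phenotype("C", "CD20", abundance = 0.1))
  spec <- tissue_spec(ph, n_cells = 10000, field_um = c(3000, 3000))
  sim <- generate_cell_table(spec, seed = 11)
  frac <- table(sim$truth$true_type) / 10000
  expect_lt(abs(frac[["A"]] - 0.6), 0.02)
  expect_lt(abs(frac[["B"]] - 0.3), 0.02)
  expect_lt(abs(frac[["C"]] - 0.1), 0.02)
})

test_that("marginal expression means follow the truncated-normal law", {
  means <- c(DAPI = 200, AF = 0, CD3 = 8, CD68 = 40)
  sds <- c(DAPI = 20, AF = 0, CD3 = 6, CD68 = 15)
  panel <- marker_panel(names(means), 0.5)
  ph <- phenotype_spec("A", means, sds, abundance = 1)
  spec <- tissue_spec(list(ph), n_cells = 10000, field_um = c(3000, 3000),
                      panel = panel)
  sim <- generate_cell_table(spec, seed = 5)
  for (m in c("CD3", "CD68")) {
    expected <- mxifcell:::truncnorm_mean(means[[m]], sds[[m]])
    se <- sds[[m]] / sqrt(10000)
    expect_lt(abs(mean(sim$cells[[m]]) - expected), 3 * se)
  }
})

test_that("CSR placements are spatially random (Clark-Evans near 1)", {
  spec <- tissue_spec(default_phenotypes(), n_cells = 2000,
                      field_um = c(1000, 1000))
  ce <- vapply(1:3, function(s) {
    clark_evans(generate_cell_table(spec, seed = s)$cells, c(1000, 1000))
  }, numeric(1))
  expect_true(all(abs(ce - 1) < 0.05))
})

test_that("clustered and avoidance spatial models shape the pattern", {
  ph <- list(mk_phenotype("A", "CD3", abundance = 0.5),
             mk_phenotype("B", "CD68", abundance = 0.5))
  spec_cl <- tissue_spec(ph, n_cells = 600, field_um = c(1000, 1000),
                         spatial_model = list(model = "clustered",
                                              type = "A", parent_rate = 20,
                                              cluster_sd = 15))
  sim <- generate_cell_table(spec_cl, seed = 3)
  a <- sim$truth[sim$truth$true_type == "A", ]
  expect_lt(clark_evans(a, c(1000, 1000)), 0.8)   # aggregated

  spec_av <- tissue_spec(ph, n_cells = 300, field_um = c(1000, 1000),
                         spatial_model = list(model = "avoidance",
                                              type_a = "A", type_b = "B",
                                              min_dist_um = 60))
  sim <- generate_cell_table(spec_av, seed = 3)
  a <- sim$truth[sim$truth$true_type == "A", ]
  b <- sim$truth[sim$truth$true_type == "B", ]
  dab <- sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2)
  expect_gte(min(dab), 60)
})

test_that("rendering draws disks with background and per-round shifts", {
  panel <- marker_panel(c("DAPI", "CD3"), 0.5)
  ph <- phenotype_spec("A", c(DAPI = 200, CD3 = 100), NULL, radius_um = 4)
  spec <- tissue_spec(list(ph), n_cells = 1, field_um = c(50, 50),
                      panel = panel, af_level = 0, noise_sd = 0)
  sim <- generate_cell_table(spec, seed = 2)
  img <- render_image(sim$cells, spec, seed = 2)[[1]]
  cd3 <- get_channel(img, "CD3")
  nz <- which(cd3 > 0, arr.ind = TRUE)
  px <- panel$pixel_size_um
  d <- sqrt(((nz[, 1] - 1) * px - sim$cells$y_um)^2 +
            ((nz[, 2] - 1) * px - sim$cells$x_um)^2)
  expect_true(all(d <= 4 + px))  # all signal inside the disk footprint
  expect_true(all(cd3[cd3 > 0] == 100))

  # zero shifts: every round's DAPI is identical
  spec4 <- tissue_spec(list(mk_phenotype("A", "CD3")), n_cells = 20,
                       field_um = c(120, 120), min_dist_um = 12,
                       noise_sd = 0)
  sim4 <- generate_cell_table(spec4, seed = 3)
  rounds <- render_image(sim4$cells, spec4, seed = 3)
  d1 <- get_channel(rounds[[1]], "DAPI")
  for (r in 2:4) expect_equal(get_channel(rounds[[r]], "DAPI"), d1)

  # determinism
  rounds2 <- render_image(sim4$cells, spec4, seed = 3)
  expect_identical(rounds[[2]]$channels, rounds2[[2]]$channels)

  # out-of-field cells are a placement error
  bad <- sim4$cells
  bad$x_um[1] <- 500
  expect_error(render_image(bad, spec4, seed = 1), "placement error")
})

test_that("dim-DAPI phenotypes render proportionally dimmer nuclei", {
  panel <- marker_panel(c("DAPI", "CD68"), 0.5)
  mac <- phenotype_spec("Mac", c(DAPI = 200, CD68 = 100), NULL,
                        dapi_intensity_factor = 0.2, radius_um = 4,
                        abundance = 0.5)
  tc <- phenotype_spec("T", c(DAPI = 200, CD68 = 0), NULL,
                       dapi_intensity_factor = 1, radius_um = 4,
                       abundance = 0.5)
  spec <- tissue_spec(list(mac, tc), n_cells = 40, field_um = c(300, 300),
                      panel = panel, af_level = 0, noise_sd = 0,
                      min_dist_um = 12)
  sim <- generate_cell_table(spec, seed = 6)
  img <- render_image(sim$cells, spec, seed = 6)[[1]]
  dapi <- get_channel(img, "DAPI")
  disk_mean <- function(row) {
    px <- 0.5
    cy <- row$y_um / px; cx <- row$x_um / px
    yy <- outer((seq_len(nrow(dapi)) - 1 - cy)^2, rep(1, ncol(dapi)))
    xx <- outer(rep(1, nrow(dapi)), (seq_len(ncol(dapi)) - 1 - cx)^2)
    mean(dapi[yy + xx <= (3 / px)^2])   # interior of the disk
  }
  m_mac <- disk_mean(sim$cells[sim$truth$true_type == "Mac", ][1, ])
  m_t <- disk_mean(sim$cells[sim$truth$true_type == "T", ][1, ])
  expect_lt(abs(m_mac / m_t - 0.2), 0.05 * 0.2 + 0.01)
})
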