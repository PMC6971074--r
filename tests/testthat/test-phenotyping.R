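test_that("normalization yields zero-mean unit-sd markers with clipping", {
  set.seed(10)
  tbl <- tibble::tibble(cell_id = 1:500, case_id = "t", x_um = 0, y_um = 0,
                        area_um2 = 1,
                        CD3 = rnorm(500, 50, 10),
                        CD68 = rexp(500, 1 / 30),
                        FLAT = rep(4, 500))
  expect_warning(out <- normalize_expression(tbl), "constant")
  for (m in c("CD3", "CD68")) {
    expect_lt(abs(mean(out[[m]])), 1e-9)
    expect_lt(abs(stats::sd(out[[m]]) - 1), 1e-9)
  }
  expect_true(all(out$FLAT == 0))

  # an extreme outlier is clipped to the 99th percentile before scaling
  tbl2 <- tbl[, !(names(tbl) %in% "FLAT")]
  tbl2$CD3[1] <- 50000
  out2 <- normalize_expression(tbl2)
  clipped <- pmin(tbl2$CD3, stats::quantile(tbl2$CD3, 0.99, names = FALSE))
  oracle_max <- (max(clipped) - mean(clipped)) / stats::sd(clipped)
  expect_lte(max(out2$CD3), oracle_max + 1e-9)

  expect_error(normalize_expression(tbl[1, ]), "at least 2")
})

test_that("arcsinh normalization compresses the heavy tail", {
  set.seed(11)
  tbl <- tibble::tibble(cell_id = 1:300, case_id = "t", x_um = 0, y_um = 0,
                        area_um2 = 1, CD3 = rexp(300, 1 / 100))
  z <- normalize_expression(tbl, method = "zscore")
  a <- normalize_expression(tbl, method = "arcsinh", cofactor = 5)
  expect_lt(abs(mean(a$CD3)), 1e-9)
  expect_lt(max(a$CD3), max(z$CD3))  # tail compressed
})

test_that("phenograph separates well-separated blobs perfectly", {
  set.seed(12)
  n <- 400
  truth <- rep(1:2, each = n / 2)
  tbl <- tibble::tibble(cell_id = 1:n, case_id = "t", x_um = 0, y_um = 0,
                        area_um2 = 1,
                        M1 = rnorm(n, ifelse(truth == 1, 0, 10), 1),
                        M2 = rnorm(n, 0, 1))
  cl <- cluster_phenograph(tbl, k = 15, seed = 1)
  expect_equal(max(cl$cluster_id), 2)
  expect_equal(adjusted_rand_index(cl$cluster_id, truth), 1)
  # agreement with the independent pair-counting implementation
  expect_equal(adjusted_rand_index(cl$cluster_id, truth),
               mclust::adjustedRandIndex(cl$cluster_id, truth))
})

test_that("phenograph is deterministic and handles degenerate input", {
  set.seed(13)
  tbl <- tibble::tibble(cell_id = 1:120, case_id = "t", x_um = 0, y_um = 0,
                        area_um2 = 1,
                        M1 = rnorm(120), M2 = rnorm(120))
  c1 <- cluster_phenograph(tbl, k = 10, seed = 5)
  c2 <- cluster_phenograph(tbl, k = 10, seed = 5)
  expect_identical(c1$cluster_id, c2$cluster_id)
  expect_error(cluster_phenograph(tbl, k = 120), "smaller")

  same <- dplyr::mutate(tbl, M1 = 1, M2 = 2)
  cl <- cluster_phenograph(same, k = 10, seed = 1)
  expect_equal(max(cl$cluster_id), 1)
})

test_that("cluster profiles report means and positive fractions", {
  tbl <- tibble::tibble(cell_id = 1:10, case_id = "t", x_um = 0, y_um = 0,
                        area_um2 = 1, cluster_id = 1L,
                        CD3 = rep(2, 10), CD8 = seq(-1, 1, length.out = 10))
  prof <- profile_clusters(tbl)
  expect_equal(prof$frac_positive[prof$marker == "CD3"], 1)
  expect_equal(prof$mean_expr[prof$marker == "CD3"], 2)
  profInf <- profile_clusters(tbl, thresholds = c(CD3 = Inf, CD8 = Inf))
  expect_true(all(profInf$frac_positive == 0))
})

test_that("a synthetic CD8 T-cell cluster profiles as CD3+ CD8+", {
  spec <- tissue_spec(default_phenotypes(tumor_fraction = 0.4),
                      n_cells = 2000, field_um = c(1500, 1500))
  sim <- generate_cell_table(spec, seed = 14)
  norm <- suppressWarnings(normalize_expression(sim$cells))
  norm$cluster_id <- as.integer(factor(sim$truth$true_type))
  prof <- profile_clusters(norm)
  cd8_cluster <- unique(norm$cluster_id[sim$truth$true_type == "CD8_T"])
  fp <- prof[prof$cluster_id == cd8_cluster, ]
  expect_gte(fp$frac_positive[fp$marker == "CD3"], 1 / 3)
  expect_gte(fp$frac_positive[fp$marker == "CD8"], 1 / 3)
})

test_that("the rule engine reproduces the published phenotype definitions", {
  rules <- cell_type_rules()
  expect_setequal(rules$type_name,
                  c("CD4_T", "CD8_T", "NK", "B", "TAM", "Histiocyte",
                    "Phagocyte", "InflammatoryMonocyte",
                    "MonoMac_undefined"))
  # TAM: CD16 plus restricted lineage markers CD68, CD163
  tam <- c(CD16 = 0.8, CD68 = 0.9, CD163 = 0.7, CD3 = 0.05, CD45 = 0.9)
  expect_equal(classify_cluster(tam, rules), "TAM")
  # NK: CD45+, CD3-, GranzymeB and Granulysin
  nk <- c(CD45 = 0.9, CD3 = 0.1, GranzymeB = 0.6, Granulysin = 0.5)
  expect_equal(classify_cluster(nk, rules), "NK")
  # inflammatory monocyte: LYZ+ VISTA+, CD68- CD163-
  im <- c(LYZ = 0.5, VISTA = 0.4, CD68 = 0.1, CD163 = 0.05)
  expect_equal(classify_cluster(im, rules), "InflammatoryMonocyte")
  # nothing expressed
  blank <- stats::setNames(rep(0, 6),
                           c("CD45", "CD3", "CD68", "CD163", "LYZ", "CD16"))
  expect_equal(classify_cluster(blank, rules), "Unassigned")
})

test_that("classification ignores marker order and unrelated markers", {
  rules <- cell_type_rules()
  tam <- c(CD16 = 0.8, CD68 = 0.9, CD163 = 0.7)
  expect_equal(classify_cluster(tam[c(3, 1, 2)], rules), "TAM")
  tam_extra <- c(tam, XYZ1 = 0.99, XYZ2 = 0.01)
  expect_equal(classify_cluster(tam_extra, rules), "TAM")
})

test_that("equal-priority matches raise an explicit tie error", {
  rules <- tibble::tibble(
    type_name = c("TAM", "Histiocyte"),
    required_positive = list("CD68", "CD68"),
    required_negative = list(character(0), character(0)),
    priority = c(5L, 5L))
  expect_error(classify_cluster(c(CD68 = 0.9), rules), "tie")
})

test_that("the exhaustion-state caller covers its decision space", {
  mk_case <- function(n_cd4, n_cd8, n_nk, pd1, tcf7) {
    n <- n_cd4 + n_cd8 + n_nk
    kp <- round(pd1 * n_cd8); kt <- round(tcf7 * n_cd8)
    tibble::tibble(
      cell_id = seq_len(n),
      case_id = "t",
      cell_type = rep(c("CD4_T", "CD8_T", "NK"), c(n_cd4, n_cd8, n_nk)),
      PD1 = c(rep(0, n_cd4), rep(c(1, 0), c(kp, n_cd8 - kp)), rep(0, n_nk)),
      TCF7 = c(rep(0, n_cd4), rep(c(1, 0), c(kt, n_cd8 - kt)),
               rep(0, n_nk)))
  }
  # fewer than 60 lymphocytes per mm2 is a deserted case
  out <- classify_tcell_state(mk_case(10, 15, 5, 0.9, 0.1), area_mm2 = 1)
  expect_equal(out$state, "Deserted")
  expect_equal(out$lymphocyte_density_per_mm2, 30)
  # boundary: 59 vs 60 lymphocytes on 1 mm2
  expect_equal(classify_tcell_state(mk_case(0, 59, 0, 0.8, 0),
                                    area_mm2 = 1)$state, "Deserted")
  expect_equal(classify_tcell_state(mk_case(0, 60, 0, 0.8, 0),
                                    area_mm2 = 1)$state, "T_ex_acute")
  # PD1-high TCF7-low: acute; TCF7-present PD1-low: chronic; both: mixed
  expect_equal(classify_tcell_state(mk_case(50, 100, 10, 0.8, 0.05),
                                    area_mm2 = 1)$state, "T_ex_acute")
  expect_equal(classify_tcell_state(mk_case(50, 100, 10, 0.1, 0.6),
                                    area_mm2 = 1)$state, "T_ex_chronic")
  expect_equal(classify_tcell_state(mk_case(50, 100, 10, 0.5, 0.5),
                                    area_mm2 = 1)$state, "T_ex_mixed")
  # exactly one state over a grid spanning all four branches
  for (pd1 in c(0, 0.2, 0.4, 0.8)) {
    for (tcf7 in c(0, 0.2, 0.4, 0.8)) {
      st <- classify_tcell_state(mk_case(0, 100, 0, pd1, tcf7),
                                 area_mm2 = 1)$state
      expect_length(st, 1)
      expect_true(st %in% c("T_ex_acute", "T_ex_chronic", "T_ex_mixed",
                            "Deserted"))
    }
  }
  # dense case with no CD8 T cells: warning, called Deserted
  no_cd8 <- tibble::tibble(cell_id = 1:100, case_id = "t",
                           cell_type = rep("CD4_T", 100),
                           PD1 = 0, TCF7 = 0)
  expect_warning(out <- classify_tcell_state(no_cd8, area_mm2 = 1),
                 "no CD8")
  expect_equal(out$state, "Deserted")
})

test_that("composition percentages cover typed cells and sum to 100", {
  tbl <- tibble::tibble(cell_type = rep(c("TAM", "CD8_T"), each = 50))
  comp <- composition(tbl)
  expect_equal(sort(comp$pct), c(50, 50))
  expect_equal(sum(comp$pct), 100)

  one <- composition(tibble::tibble(cell_type = rep("NK", 7)))
  expect_equal(one$pct, 100)

  mixed <- tibble::tibble(cell_type = c(rep("TAM", 30), rep("Unassigned", 70)))
  expect_equal(composition(mixed)$pct, 100)

  expect_equal(nrow(composition(tibble::tibble(cell_type = character(0)))), 0)
  expect_equal(nrow(composition(
    tibble::tibble(cell_type = rep("Unassigned", 5)))), 0)
})
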