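#' Run the full analysis pipeline on a synthetic tissue
#'
#' End-to-end convenience wrapper: simulate a ground-truthed tissue,
#' render and register the staining rounds, subtract autofluorescence,
#' build the nuclear and targeted masks, quantify cells from the targeted
#' mask, normalize, cluster, profile and classify them, call the case's
#' T-cell exhaustion state and run the neighbourhood permutation test.
#'
#' @param spec A [tissue_spec()]; defaults to 600 cells of the default
#'   phenotype mixture.
#' @param seed Integer seed driving every stochastic step.
#' @param k Phenograph neighbours (default 30).
#' @param n_permutations Neighbourhood permutations (default 200).
#' @param rules Cell-type rule tibble.
#' @return A list with `cells` (typed single-cell tibble), `truth`,
#'   `registration`, `nuclear_mask`, `targeted_mask`, `mask_yield`,
#'   `profiles`, `composition`, `tcell_state` and `neighborhood`.
#' @export
run_pipeline <- function(spec = NULL, seed = 1, k = 30,
                         n_permutations = 200,
                         rules = cell_type_rules()) {
  if (is.null(spec)) {
    spec <- tissue_spec(default_phenotypes(), n_cells = 600,
                        field_um = c(500, 500), min_dist_um = 13)
  }
  sim <- generate_cell_table(spec, seed = seed)
  rounds <- render_image(sim$cells, spec, seed = seed + 1)
  reg <- register_rounds(rounds)
  img <- if ("AF" %in% reg$image$panel$markers) {
    subtract_autofluorescence(reg$image, "AF")
  } else reg$image
  nuc <- make_nuclear_mask(img)
  tar <- make_targeted_mask(img)
  cells <- quantify(img, tar, case_id = "synthetic")
  area_mm2 <- prod(spec$field_um) / 1e6
  norm <- normalize_expression(cells)
  norm <- cluster_phenograph(norm, k = min(k, nrow(norm) - 1), seed = seed)
  profiles <- profile_clusters(norm)
  typed <- assign_cell_types(norm, profiles, rules)
  nb <- interaction_test(typed[!is.na(typed$cell_type) &
                               typed$cell_type != "Unassigned", ],
                         n_permutations = n_permutations, seed = seed)
  list(cells = typed, truth = sim$truth, registration = reg$registration,
       nuclear_mask = nuc, targeted_mask = tar,
       mask_yield = compare_mask_yield(nuc, tar),
       profiles = profiles, composition = composition(typed),
       tcell_state = classify_tcell_state(typed, area_mm2),
       neighborhood = nb)
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement between two partitions, corrected for chance;
#' 1 means identical partitions, 0 the chance level. Used to score
#' clustering against simulation ground truth.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  ct <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(ct))
  sum_a <- sum(comb2(rowSums(ct)))
  sum_b <- sum(comb2(colSums(ct)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
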