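#' Normalize marker expression
#'
#' Per marker: values are clipped above the `clip_percentile` quantile,
#' optionally arcsinh-transformed (`asinh(x / cofactor)`), and z-scored.
#' After normalization every non-constant marker column has mean 0 and sd 1;
#' constant columns become all-zero with a warning.
#'
#' @param table Single-cell tibble (>= 2 rows).
#' @param markers Marker columns; defaults to [marker_columns()].
#' @param clip_percentile Upper clipping percentile in (90, 100\].
#' @param method `"zscore"` or `"arcsinh"` (arcsinh then z-score).
#' @param cofactor Arcsinh cofactor (> 0), used by `method = "arcsinh"`.
#' @return The table with marker columns replaced by normalized values.
#' @export
normalize_expression <- function(table, markers = NULL,
                                 clip_percentile = 99,
                                 method = c("zscore", "arcsinh"),
                                 cofactor = 5) {
  method <- match.arg(method)
  if (nrow(table) < 2) {
    stop("normalization needs at least 2 cells", call. = FALSE)
  }
  stopifnot(clip_percentile > 90, clip_percentile <= 100, cofactor > 0)
  if (is.null(markers)) markers <- marker_columns(table)
  for (m in markers) {
    x <- table[[m]]
    q <- stats::quantile(x, clip_percentile / 100, names = FALSE)
    x <- pmin(x, q)
    if (method == "arcsinh") x <- asinh(x / cofactor)
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      warning(sprintf("marker '%s' is constant; normalized to 0", m),
              call. = FALSE)
      table[[m]] <- rep(0, length(x))
    } else {
      table[[m]] <- (x - mean(x)) / s
    }
  }
  table
}

# Exact k-nearest-neighbour indices (Euclidean), chunked; ties broken by
# row index (stable order()), so results are deterministic.
knn_indices <- function(X, k, chunk = 1000L) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  idx <- matrix(0L, n, k)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    D <- -2 * tcrossprod(X[s:e, , drop = FALSE], X)
    D <- sweep(D, 2, sq, "+")
    for (i in seq_len(e - s + 1L)) {
      d <- D[i, ]
      d[s + i - 1L] <- Inf
      idx[s + i - 1L, ] <- order(d)[seq_len(k)]
    }
  }
  idx
}

#' Phenograph-style clustering
#'
#' Builds the exact k-nearest-neighbour graph in marker space (Euclidean),
#' reweights each kNN edge by the Jaccard overlap of the two cells'
#' neighbour sets, and partitions the graph by Louvain modularity
#' optimization. Cluster ids are relabelled 1..C by decreasing size.
#' Deterministic given `(table, k, seed)`.
#'
#' @param table Normalized single-cell tibble.
#' @param markers Marker columns used; defaults to [marker_columns()].
#' @param k Number of neighbours (default 30, must be < number of cells).
#' @param seed Integer seed for the Louvain optimization.
#' @param resolution Louvain resolution parameter (default 0.1). Values
#'   below 1 coarsen the partition; plain modularity (resolution 1)
#'   shatters even a single compact expression mode into several
#'   sub-communities on kNN graphs, so the default is chosen low enough
#'   that one well-separated mode stays one cluster while distinct modes,
#'   being (almost) disconnected in the kNN graph, still cannot merge.
#' @return The table with an integer `cluster_id` column added.
#' @export
cluster_phenograph <- function(table, markers = NULL, k = 30, seed = 1,
                               resolution = 0.1) {
  if (is.null(markers)) markers <- marker_columns(table)
  n <- nrow(table)
  if (k >= n) stop("`k` must be smaller than the number of cells",
                   call. = FALSE)
  stopifnot(k >= 1)
  X <- as.matrix(table[, markers])
  nb <- knn_indices(X, k)
  ei <- rep(seq_len(n), k)
  ej <- as.vector(nb)
  S <- Matrix::sparseMatrix(i = ei, j = ej, x = 1, dims = c(n, n))
  # undirected unique edge list
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  eid <- !duplicated(lo + (hi - 1) * as.double(n))
  lo <- lo[eid]; hi <- hi[eid]
  shared <- numeric(length(lo))
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  chunk <- 2000L
  for (s in seq(1, length(lo), by = chunk)) {
    e <- min(s + chunk - 1L, length(lo))
    rows <- unique(lo[s:e])
    P <- Matrix::tcrossprod(S[rows, , drop = FALSE], S)
    shared[s:e] <- P[cbind(match(lo[s:e], rows), hi[s:e])]
  }
  jac <- shared / (2 * k - shared)
  g <- igraph::graph_from_edgelist(cbind(lo, hi), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- pmax(jac, 1e-10)
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                  resolution = resolution)
  mem <- as.integer(igraph::membership(comm))
  sizes <- table(mem)
  relabel <- match(mem, as.integer(names(sort(sizes, decreasing = TRUE))))
  dplyr::mutate(table, cluster_id = as.integer(relabel))
}

#' Profile phenoclusters
#'
#' Per cluster and marker: the mean normalized expression and the fraction
#' of the cluster's cells whose normalized value exceeds the positivity
#' threshold. This long table is the numeric form of the cluster heatmap
#' that the cell-type rules are applied to.
#'
#' @param table Normalized tibble with `cluster_id`.
#' @param markers Marker columns; defaults to [marker_columns()].
#' @param threshold Positivity threshold in normalized units (default 0.5).
#' @param thresholds Optional named vector of per-marker overrides.
#' @return Long tibble: `cluster_id`, `n_cells`, `marker`, `mean_expr`,
#'   `frac_positive`.
#' @export
profile_clusters <- function(table, markers = NULL, threshold = 0.5,
                             thresholds = NULL) {
  if (!"cluster_id" %in% names(table)) {
    stop("table has no `cluster_id`; run cluster_phenograph() first",
         call. = FALSE)
  }
  if (is.null(markers)) markers <- marker_columns(table)
  thr <- stats::setNames(rep(threshold, length(markers)), markers)
  if (!is.null(thresholds)) thr[names(thresholds)] <- thresholds
  long <- tidyr::pivot_longer(
    table[, c("cluster_id", markers)], cols = dplyr::all_of(markers),
    names_to = "marker", values_to = "value")
  long$thr <- thr[long$marker]
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$cluster_id, .data$marker),
    n_cells = dplyr::n(),
    mean_expr = mean(.data$value),
    frac_positive = mean(.data$value > .data$thr[1]),
    .groups = "drop")
  dplyr::arrange(out[, c("cluster_id", "n_cells", "marker", "mean_expr",
                         "frac_positive")],
                 .data$cluster_id, match(.data$marker, markers))
}

#' Cell-type classification rules
#'
#' Reads a rule table (YAML) for the nine-type classification of the
#' inflammatory infiltrate. Each rule has `type_name`, `required_positive`
#' and `required_negative` marker lists, and a `priority`; a cluster
#' matches a rule when every required-positive marker is expressed at high
#' level in at least a third of its cells and every required-negative
#' marker in less than a third.
#'
#' @param path Rules YAML; defaults to the rule table shipped with the
#'   package, reconstructed from the published phenotype definitions.
#' @return Tibble with list-columns `required_positive`,
#'   `required_negative`.
#' @export
cell_type_rules <- function(path = system.file("extdata",
                                               "cell_type_rules.yaml",
                                               package = "mxifcell")) {
  y <- yaml::read_yaml(path)
  rules <- tibble::tibble(
    type_name = vapply(y$rules, `[[`, character(1), "type_name"),
    required_positive = lapply(y$rules, function(r)
      as.character(unlist(r$required_positive))),
    required_negative = lapply(y$rules, function(r)
      as.character(unlist(r$required_negative))),
    priority = vapply(y$rules, function(r) as.integer(r$priority),
                      integer(1)))
  allowed <- c("CD4_T", "CD8_T", "NK", "B", "TAM", "Histiocyte",
               "Phagocyte", "InflammatoryMonocyte", "MonoMac_undefined")
  bad <- setdiff(rules$type_name, allowed)
  if (length(bad) > 0) {
    stop(sprintf("unknown cell type(s) in rules: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (i in seq_len(nrow(rules))) {
    if (length(intersect(rules$required_positive[[i]],
                         rules$required_negative[[i]])) > 0) {
      stop(sprintf("rule '%s' lists a marker as both positive and negative",
                   rules$type_name[i]), call. = FALSE)
    }
  }
  rules
}

#' Classify one cluster profile
#'
#' A rule matches iff `frac_positive >= 1/3` for every required-positive
#' marker and `frac_positive < 1/3` for every required-negative marker
#' (the published criterion: a defining marker must be expressed at high
#' level in a third or more of the cluster's cells). Among matching rules
#' the highest priority wins; equal priorities among matches raise an
#' error; no match returns `"Unassigned"`. A required-positive marker
#' absent from the profile fails the rule; an absent required-negative
#' marker is treated as negative.
#'
#' @param profile Either a long profile tibble (rows of one cluster, as
#'   from [profile_clusters()]) or a named numeric vector of
#'   `frac_positive` per marker.
#' @param rules Rule tibble from [cell_type_rules()].
#' @param frac_required Fraction-of-cells criterion (default 1/3).
#' @return A cell-type name or `"Unassigned"`.
#' @export
classify_cluster <- function(profile, rules = cell_type_rules(),
                             frac_required = 1 / 3) {
  if (is.data.frame(profile)) {
    if (length(unique(profile$cluster_id %||% 1)) > 1) {
      stop("`profile` must describe a single cluster", call. = FALSE)
    }
    fp <- stats::setNames(profile$frac_positive, profile$marker)
  } else {
    fp <- profile
  }
  matches <- vapply(seq_len(nrow(rules)), function(i) {
    pos <- rules$required_positive[[i]]
    neg <- rules$required_negative[[i]]
    if (!all(pos %in% names(fp))) return(FALSE)
    if (any(fp[pos] < frac_required)) return(FALSE)
    neg_in <- intersect(neg, names(fp))
    all(fp[neg_in] < frac_required)
  }, logical(1))
  if (!any(matches)) return("Unassigned")
  pr <- rules$priority[matches]
  top <- max(pr)
  if (sum(pr == top) > 1) {
    stop(sprintf("rule tie: types %s match at equal priority %d",
                 paste(rules$type_name[matches][pr == top], collapse = ", "),
                 top), call. = FALSE)
  }
  rules$type_name[matches][which.max(pr)]
}

#' Assign cell types to clustered cells
#'
#' Classifies every cluster profile with the rule engine and joins the
#' resulting type onto the per-cell table.
#'
#' @param table Tibble with `cluster_id`.
#' @param profiles Long profile tibble from [profile_clusters()].
#' @param rules Rule tibble.
#' @inheritParams classify_cluster
#' @return The table with a `cell_type` column added.
#' @export
assign_cell_types <- function(table, profiles, rules = cell_type_rules(),
                              frac_required = 1 / 3) {
  ids <- sort(unique(profiles$cluster_id))
  types <- vapply(ids, function(cid) {
    classify_cluster(profiles[profiles$cluster_id == cid, ], rules,
                     frac_required)
  }, character(1))
  map <- stats::setNames(types, ids)
  dplyr::mutate(table, cell_type = unname(map[as.character(.data$cluster_id)]))
}

#' Per-case predominant T-cell exhaustion state
#'
#' Operationalizes the exhaustion-state call: a case with fewer than
#' `deserted_density` lymphocytes (CD4 T + CD8 T + NK) per square
#' millimetre is `Deserted`; otherwise the fractions of PD1-positive and
#' TCF7-positive CD8 T cells decide between acute exhaustion (PD1-high,
#' TCF7-low), chronic exhaustion (TCF7-present, PD1-low) and a mixed
#' state (both). A case above the density cut whose PD1 and TCF7 fractions
#' are both below their thresholds shows no exhaustion phenotype and is
#' called `Deserted`; so is a case above the cut with no CD8 T cells (with
#' a warning).
#'
#' @param table Single-cell tibble with `cell_type` and normalized marker
#'   columns.
#' @param area_mm2 Analyzed area, square millimetres.
#' @param theta_hi PD1-fraction threshold (default 0.33).
#' @param theta_lo TCF7-fraction threshold (default 0.33).
#' @param positivity_threshold Per-cell positivity cut in normalized units
#'   (default 0.5, as in [profile_clusters()]).
#' @param pd1_marker,tcf7_marker Column names of the two markers.
#' @param deserted_density Lymphocyte density cut, cells per square
#'   millimetre (default 60).
#' @return One-row tibble: `case_id`, `state`,
#'   `lymphocyte_density_per_mm2`, `pd1_frac`, `tcf7_frac`.
#' @export
classify_tcell_state <- function(table, area_mm2, theta_hi = 0.33,
                                 theta_lo = 0.33,
                                 positivity_threshold = 0.5,
                                 pd1_marker = "PD1", tcf7_marker = "TCF7",
                                 deserted_density = 60) {
  stopifnot(area_mm2 > 0)
  case_id <- if ("case_id" %in% names(table) && nrow(table) > 0) {
    as.character(table$case_id[1])
  } else "case"
  lymph <- table$cell_type %in% c("CD4_T", "CD8_T", "NK")
  dens <- sum(lymph) / area_mm2
  cd8 <- table[table$cell_type %in% "CD8_T", ]
  pd1_frac <- if (nrow(cd8) > 0) {
    mean(cd8[[pd1_marker]] > positivity_threshold)
  } else NA_real_
  tcf7_frac <- if (nrow(cd8) > 0) {
    mean(cd8[[tcf7_marker]] > positivity_threshold)
  } else NA_real_
  state <- if (dens < deserted_density) {
    "Deserted"
  } else if (nrow(cd8) == 0) {
    warning("density above the cut but no CD8 T cells; calling Deserted",
            call. = FALSE)
    "Deserted"
  } else if (pd1_frac >= theta_hi && tcf7_frac < theta_lo) {
    "T_ex_acute"
  } else if (tcf7_frac >= theta_lo && pd1_frac < theta_hi) {
    "T_ex_chronic"
  } else if (pd1_frac >= theta_hi && tcf7_frac >= theta_lo) {
    "T_ex_mixed"
  } else {
    "Deserted"
  }
  tibble::tibble(case_id = case_id, state = state,
                 lymphocyte_density_per_mm2 = dens,
                 pd1_frac = pd1_frac, tcf7_frac = tcf7_frac)
}

#' Infiltrate composition
#'
#' Percentage of each assigned cell type among all typed (non-Unassigned)
#' inflammatory cells; percentages sum to 100.
#'
#' @param table Tibble with `cell_type`.
#' @return Tibble: `cell_type`, `n`, `pct`. Zero typed cells give zero
#'   rows.
#' @export
composition <- function(table) {
  typed <- table[!is.na(table$cell_type) &
                 table$cell_type != "Unassigned", ]
  if (nrow(typed) == 0) {
    return(tibble::tibble(cell_type = character(0), n = integer(0),
                          pct = numeric(0)))
  }
  out <- dplyr::count(typed, .data$cell_type)
  out$pct <- 100 * out$n / sum(out$n)
  out
}
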