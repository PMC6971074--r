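#' Neighbour sets within a spatial range
#'
#' Cells are neighbours when their centroid distance falls in the range:
#' a single radius `r` means distance in `[0, r]` (self excluded), a
#' two-value annulus `c(lo, hi)` means distance in `(lo, hi]`.
#'
#' @param cells Tibble with `x_um`, `y_um` (micrometres).
#' @param range Radius (length 1) or annulus bounds (length 2).
#' @return List of integer index vectors, one per cell.
#' @export
build_neighbor_sets <- function(cells, range) {
  stopifnot(nrow(cells) >= 1, length(range) %in% 1:2, all(range >= 0))
  n <- nrow(cells)
  D <- as.matrix(stats::dist(cbind(cells$x_um, cells$y_um)))
  lo <- if (length(range) == 2) range[1] else -1
  hi <- if (length(range) == 2) range[2] else range[1]
  if (length(range) == 2 && range[1] >= range[2]) {
    stop("annulus inner bound must be below the outer bound", call. = FALSE)
  }
  A <- D > lo & D <= hi
  diag(A) <- FALSE
  lapply(seq_len(n), function(i) as.integer(which(A[i, ])))
}

range_adjacency <- function(D, lo, hi) {
  A <- D > lo & D <= hi
  diag(A) <- FALSE
  storage.mode(A) <- "double"
  A
}

#' Permutation test of pairwise phenotype interaction and avoidance
#'
#' For every ordered phenotype pair (A, B) and each of two spatial ranges
#' -- a short radius (submicroscopic, default within 100 um) and a long
#' annulus (microscopic, default 100--250 um) -- the observed statistic is
#' the mean number of B-neighbours per A-cell. The null is built by
#' shuffling the type labels over the fixed cell positions
#' `n_permutations` times; empirical add-one p-values are reported for
#' enrichment (null >= observed) and avoidance (null <= observed), so
#' p-values are never smaller than `1 / (n_permutations + 1)`. Significance
#' flags use `p < alpha` (strict). Pairs involving a type with zero cells
#' are reported as `NA`. Deterministic given `seed`.
#'
#' @param cells Tibble with `x_um`, `y_um` and `cell_type` (character or
#'   factor; unused factor levels are kept and reported as `NA`).
#' @param short_radius_um Short-range radius (default 100).
#' @param long_range_um Long-range annulus, `c(inner, outer]` (default
#'   `c(100, 250)`).
#' @param n_permutations Number of label permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @param adjust `"none"` (default) or `"BH"` (Benjamini-Hochberg across
#'   pairs within each range, applied to both p-value columns before
#'   flagging).
#' @return Long tibble: `range` (`"short"`/`"long"`), `type_a`, `type_b`,
#'   `observed`, `p_enrich`, `p_avoid`, `significant_enrich`,
#'   `significant_avoid`.
#' @export
interaction_test <- function(cells, short_radius_um = 100,
                             long_range_um = c(100, 250),
                             n_permutations = 1000, alpha = 0.05,
                             seed = 1, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(short_radius_um > 0, length(long_range_um) == 2,
            long_range_um[1] < long_range_um[2], n_permutations >= 1)
  types <- factor(cells$cell_type)
  lev <- levels(types)
  K <- length(lev)
  n <- nrow(cells)
  n_per <- as.numeric(table(types))
  Tm <- matrix(0, n, K)
  Tm[cbind(seq_len(n), as.integer(types))] <- 1
  D <- as.matrix(stats::dist(cbind(cells$x_um, cells$y_um)))
  ranges <- list(short = c(-1, short_radius_um),
                 long = c(long_range_um[1], long_range_um[2]))
  set.seed(as.integer(seed))
  perms <- replicate(n_permutations, sample.int(n), simplify = FALSE)
  res <- list()
  for (rn in names(ranges)) {
    A <- range_adjacency(D, ranges[[rn]][1], ranges[[rn]][2])
    obs_cnt <- crossprod(Tm, A %*% Tm)   # K x K neighbour-pair counts
    ge <- matrix(0, K, K); le <- matrix(0, K, K)
    for (p in perms) {
      Tp <- Tm[p, , drop = FALSE]
      M <- crossprod(Tp, A %*% Tp)
      ge <- ge + (M >= obs_cnt)
      le <- le + (M <= obs_cnt)
    }
    p_enrich <- (1 + ge) / (n_permutations + 1)
    p_avoid <- (1 + le) / (n_permutations + 1)
    observed <- sweep(obs_cnt, 1, pmax(n_per, 1), "/")
    grid <- expand.grid(a = seq_len(K), b = seq_len(K))
    tb <- tibble::tibble(
      range = rn,
      type_a = lev[grid$a], type_b = lev[grid$b],
      observed = observed[cbind(grid$a, grid$b)],
      p_enrich = p_enrich[cbind(grid$a, grid$b)],
      p_avoid = p_avoid[cbind(grid$a, grid$b)])
    empty <- n_per[grid$a] == 0 | n_per[grid$b] == 0
    tb$observed[empty] <- NA_real_
    tb$p_enrich[empty] <- NA_real_
    tb$p_avoid[empty] <- NA_real_
    res[[rn]] <- tb
  }
  out <- dplyr::bind_rows(res)
  if (adjust == "BH") {
    out <- dplyr::mutate(dplyr::group_by(out, .data$range),
                         p_enrich = stats::p.adjust(.data$p_enrich, "BH"),
                         p_avoid = stats::p.adjust(.data$p_avoid, "BH"))
    out <- dplyr::ungroup(out)
  }
  out$significant_enrich <- !is.na(out$p_enrich) & out$p_enrich < alpha
  out$significant_avoid <- !is.na(out$p_avoid) & out$p_avoid < alpha
  out
}
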