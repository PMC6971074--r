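#' Tissue-core area
#'
#' Total analyzed area of `n_cores` circular tissue-microarray cores of a
#' given diameter: `n_cores * pi * (diameter / 2)^2`. Two standard 2-mm
#' cores give 6.28 mm^2 (about 40 high-power fields). The value is exact;
#' rounding belongs to presentation only.
#'
#' @param n_cores Number of cores (integer >= 1).
#' @param diameter_mm Core diameter in millimetres (> 0).
#' @return Area in square millimetres.
#' @export
#' @examples
#' core_area(2, 2)   # 6.283185
core_area <- function(n_cores = 2, diameter_mm = 2) {
  if (!is.numeric(n_cores) || length(n_cores) != 1 || n_cores < 1 ||
      n_cores != round(n_cores)) {
    stop("`n_cores` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1 ||
      diameter_mm <= 0) {
    stop("`diameter_mm` must be positive", call. = FALSE)
  }
  n_cores * pi * (diameter_mm / 2)^2
}

#' Summarize a clinical cohort table
#'
#' Cohort-level aggregates of the clinical table: age mean, sample (n-1)
#' standard deviation, range; percentage post-menopausal; TNM counts
#' grouped by leading stage token (pT1/pT2/pT3, `NA` excluded); FIGO
#' counts in the reporting buckets IB, IIB, IIIB/C (IIIB and IIIC merged),
#' IVB and unknown; and verbatim counts of the predominant T-cell
#' phenotype states. Raw values keep full precision; rounding (means to 1
#' decimal, percentages to integer) happens only in the printed report.
#'
#' @param clinical Tibble from [read_clinical_table()].
#' @return An object of class `cohort_summary`.
#' @export
#' @examples
#' summarize_clinical(read_clinical_table())
summarize_clinical <- function(clinical) {
  if (nrow(clinical) == 0) {
    stop("clinical table is empty", call. = FALSE)
  }
  n <- nrow(clinical)
  age <- clinical$age
  sd_defined <- n > 1
  figo_bucket <- function(x) {
    dplyr::case_when(is.na(x) ~ "unknown",
                     x %in% c("IIIB", "IIIC") ~ "IIIB/C",
                     TRUE ~ x)
  }
  tmn <- clinical$tmn[!is.na(clinical$tmn)]
  tmn_tok <- regmatches(tmn, regexpr("^pT[0-9]", tmn))
  structure(list(
    n_cases = n,
    age_mean = mean(age),
    age_sd = if (sd_defined) stats::sd(age) else 0,
    age_sd_defined = sd_defined,
    age_min = min(age),
    age_max = max(age),
    pct_postmenopausal = 100 * mean(clinical$menopause == "Yes"),
    tmn_stage_counts = table(tmn_tok),
    figo_counts = table(figo_bucket(clinical$figo)),
    phenotype_state_counts = table(clinical$predominant_phenotype)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d cases\n", x$n_cases))
  cat(sprintf("  Age: %.1f +/- %.1f years (%d-%d)%s\n",
              x$age_mean, x$age_sd, x$age_min, x$age_max,
              if (!x$age_sd_defined) " [sd undefined at n = 1]" else ""))
  cat(sprintf("  Post-menopausal: %d%%\n", round(x$pct_postmenopausal)))
  fmt <- function(tb) paste(sprintf("%s: %d", names(tb), as.integer(tb)),
                            collapse = ", ")
  cat("  TNM: ", fmt(x$tmn_stage_counts), "\n", sep = "")
  cat("  FIGO: ", fmt(x$figo_counts), "\n", sep = "")
  cat("  Predominant T-cell phenotype: ",
      fmt(x$phenotype_state_counts), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname summarize_clinical
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(n_cases = x$n_cases, age_mean = x$age_mean,
                 age_sd = x$age_sd, age_min = x$age_min,
                 age_max = x$age_max,
                 pct_postmenopausal = x$pct_postmenopausal)
}

#' @rdname summarize_clinical
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  as_rows <- function(tb, what) {
    tibble::tibble(variable = what, level = names(tb),
                   n = as.integer(tb))
  }
  dplyr::bind_rows(as_rows(x$tmn_stage_counts, "tmn_stage"),
                   as_rows(x$figo_counts, "figo"),
                   as_rows(x$phenotype_state_counts,
                           "predominant_phenotype"))
}

#' Aggregate per-case infiltrate compositions
#'
#' Unweighted across-case mean and sample (n-1) standard deviation of each
#' cell type's percentage; a type absent from a case counts as 0% there.
#' With fewer than 2 cases the sd is `NA`.
#'
#' @param comp Tibble of per-case compositions: `case_id`, `cell_type`,
#'   `pct` (as from [composition()], bound over cases).
#' @return Tibble: `cell_type`, `mean_pct`, `sd_pct`, `n_cases`.
#' @export
aggregate_composition <- function(comp) {
  stopifnot(all(c("case_id", "cell_type", "pct") %in% names(comp)))
  n_cases <- length(unique(comp$case_id))
  full <- tidyr::complete(comp[, c("case_id", "cell_type", "pct")],
                          .data$case_id, .data$cell_type,
                          fill = list(pct = 0))
  out <- dplyr::summarise(
    dplyr::group_by(full, .data$cell_type),
    mean_pct = mean(.data$pct),
    sd_pct = if (n_cases >= 2) stats::sd(.data$pct) else NA_real_,
    .groups = "drop")
  out$n_cases <- n_cases
  out
}
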