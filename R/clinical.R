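#' Read a clinicopathologic case table
#'
#' Reads and validates the per-case clinical record used for cohort
#' summaries: demographics, staging (FIGO, TNM), tumour size, mitotic
#' count, necrosis, semiquantitative immunophenotype scores (MHC class I,
#' MHC dynamics, desmin, B7H3, Axl, IDO -- kept verbatim as strings), total
#' cell density, the segmented-over-DAPI yield percentage and the
#' predominant T-cell phenotype call.
#'
#' `figo` and `tmn` may be missing (`NA`); `menopause` must be Yes/No,
#' `necrosis` one of Present/Focal/Absent, and `predominant_phenotype` one
#' of `T_ex-acute`, `T_ex-chronic`, `T_ex-mixed`, `Deserted`.
#'
#' @param path CSV path. Defaults to the 21-case uterine leiomyosarcoma
#'   cohort shipped with the package.
#' @return A typed tibble, one row per case.
#' @export
#' @examples
#' clin <- read_clinical_table()
#' nrow(clin)
read_clinical_table <- function(path = system.file("extdata",
                                                   "clinical_cohort.csv",
                                                   package = "mxifcell")) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA", "N/A"))
  required <- c("case_id", "age", "menopause", "figo", "tmn", "size_cm",
                "mitoses_per_10hpf", "necrosis", "mhc_class_i",
                "mhc_dynamics", "desmin", "b7h3", "axl", "ido",
                "total_cells_per_mm2", "segmented_over_dapi_pct",
                "predominant_phenotype")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop(sprintf("clinical table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tbl <- tbl[, required]
  check_enum <- function(col, allowed, allow_na = FALSE) {
    v <- tbl[[col]]
    bad <- !(v %in% allowed) & !(allow_na & is.na(v))
    if (any(bad)) {
      stop(sprintf(
        "clinical table validation error: invalid %s '%s' in case %s",
        col, v[bad][1], tbl$case_id[bad][1]), call. = FALSE)
    }
  }
  check_enum("menopause", c("Yes", "No"))
  check_enum("necrosis", c("Present", "Focal", "Absent"))
  check_enum("predominant_phenotype",
             c("T_ex-acute", "T_ex-chronic", "T_ex-mixed", "Deserted"))
  if (any(tbl$age <= 0 | tbl$age >= 120)) {
    stop("clinical table validation error: age out of range (0, 120)",
         call. = FALSE)
  }
  if (any(tbl$segmented_over_dapi_pct < 0 |
          tbl$segmented_over_dapi_pct > 100, na.rm = TRUE)) {
    stop("segmented_over_dapi_pct must lie in [0, 100]", call. = FALSE)
  }
  tbl$case_id <- as.character(tbl$case_id)
  tbl
}
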