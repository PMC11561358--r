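#' Biomarker harmonization rules
#'
#' Standard pre-medication back-corrections and cleaning rules for
#' cardiometabolic biomarkers: under cholesterol-lowering medication, LDL is
#' divided by 0.7 and triglycerides by 0.8; under blood-pressure-lowering
#' medication, 15 mmHg is added to systolic and 10 mmHg to diastolic
#' pressure; glucose and HbA1c are set missing under diabetic medication;
#' values beyond 4 SD of the mean are removed; right-skewed biomarkers are
#' log-transformed before z-scoring.
#'
#' @param ldl_divisor,tg_divisor divisors applied under cholesterol
#'   medication (in (0, 1]).
#' @param sbp_offset,dbp_offset mmHg added under blood-pressure medication.
#' @param outlier_sd outlier cutoff in SD units.
#' @param log_biomarkers column names (where present) that receive a natural
#'   log before standardization.
#' @return list of class `harmonization_rules`.
#' @export
harmonization_rules <- function(ldl_divisor = 0.7, tg_divisor = 0.8,
                                sbp_offset = 15, dbp_offset = 10,
                                outlier_sd = 4,
                                log_biomarkers = c(
                                  "leucocytes", "hba1c", "glucose", "hdl",
                                  "triglycerides", "alt", "ast",
                                  "alkaline_phosphatase", "gamma_gt",
                                  "creatinine", "creatinine_clearance",
                                  "urine_albumin", "uric_acid", "tsh",
                                  "free_t3", "free_t4", "acr", "uae")) {
  stopifnot(ldl_divisor > 0, ldl_divisor <= 1,
            tg_divisor > 0, tg_divisor <= 1,
            sbp_offset >= 0, dbp_offset >= 0, outlier_sd > 0)
  structure(list(ldl_divisor = ldl_divisor, tg_divisor = tg_divisor,
                 sbp_offset = sbp_offset, dbp_offset = dbp_offset,
                 outlier_sd = outlier_sd,
                 log_biomarkers = log_biomarkers,
                 diabetic_exclusions = c("glucose", "hba1c")),
            class = "harmonization_rules")
}

#' Back-correct biomarkers for medication use
#'
#' Applies the divisor / offset rules of [harmonization_rules()] to flagged
#' samples and sets glucose and HbA1c missing for samples on diabetic
#' medication. Idempotence is enforced: the output carries a provenance
#' marker and a second application errors.
#'
#' @param pheno phenotype data.frame with medication flag columns
#'   `chol_med`, `bp_med`, `diabetic_med` and (where present) biomarker
#'   columns `ldl`, `triglycerides`, `sbp`, `dbp`, `glucose`, `hba1c`.
#' @param rules a [harmonization_rules()].
#' @return the adjusted phenotype table, with attribute `med_adjust_counts`.
#' @export
adjust_for_medication <- function(pheno, rules = harmonization_rules()) {
  if (isTRUE(attr(pheno, "med_adjusted"))) {
    stop("medication adjustment already applied to this table")
  }
  flags <- c("chol_med", "bp_med", "diabetic_med")
  miss <- setdiff(flags, names(pheno))
  if (length(miss)) stop("missing medication flag column(s): ",
                         paste(miss, collapse = ", "))
  targets <- intersect(c("ldl", "triglycerides", "sbp", "dbp", "glucose",
                         "hba1c"), names(pheno))
  for (b in targets) {
    if (any(pheno[[b]] < 0, na.rm = TRUE)) {
      stop("negative values in biomarker '", b,
           "' (check measurement units)")
    }
  }
  counts <- c(chol = 0L, bp = 0L, diabetic = 0L)
  cm <- pheno$chol_med == 1 & !is.na(pheno$chol_med)
  if ("ldl" %in% targets) pheno$ldl[cm] <- pheno$ldl[cm] / rules$ldl_divisor
  if ("triglycerides" %in% targets) {
    pheno$triglycerides[cm] <- pheno$triglycerides[cm] / rules$tg_divisor
  }
  counts["chol"] <- sum(cm)
  bm <- pheno$bp_med == 1 & !is.na(pheno$bp_med)
  if ("sbp" %in% targets) pheno$sbp[bm] <- pheno$sbp[bm] + rules$sbp_offset
  if ("dbp" %in% targets) pheno$dbp[bm] <- pheno$dbp[bm] + rules$dbp_offset
  counts["bp"] <- sum(bm)
  dm <- pheno$diabetic_med == 1 & !is.na(pheno$diabetic_med)
  for (b in intersect(rules$diabetic_exclusions, targets)) {
    pheno[[b]][dm] <- NA_real_
  }
  counts["diabetic"] <- sum(dm)
  attr(pheno, "med_adjusted") <- TRUE
  attr(pheno, "med_adjust_counts") <- counts
  pheno
}

#' Remove extreme values from a continuous series
#'
#' Single pass: the mean and SD are computed once over non-missing values
#' and entries more than `n_sd` SDs from the mean are set missing. A zero-SD
#' series is returned unchanged.
#'
#' @param values numeric vector (>= 2 non-missing values).
#' @param n_sd cutoff in SD units (default 4).
#' @return the trimmed vector, with attribute `n_removed`.
#' @export
remove_outliers <- function(values, n_sd = 4) {
  if (sum(!is.na(values)) < 2) {
    stop("need at least 2 non-missing values")
  }
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  out <- values
  n_removed <- 0L
  if (is.finite(s) && s > 0) {
    drop <- !is.na(values) & abs(values - m) > n_sd * s
    out[drop] <- NA_real_
    n_removed <- sum(drop)
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Log-transform listed biomarkers and z-score all continuous measures
#'
#' Natural log is applied to the biomarkers named in the rules (non-positive
#' values become missing, with a count); every continuous biomarker column
#' is then z-scored over its non-missing values.
#'
#' @param pheno phenotype data.frame (outliers already removed).
#' @param rules a [harmonization_rules()].
#' @param biomarkers character vector of continuous biomarker columns to
#'   standardize; defaults to the intersection of the table's columns with
#'   the package's biomarker vocabulary.
#' @return transformed table with attribute `log_failures` (named counts).
#' @export
transform_and_standardize <- function(pheno,
                                      rules = harmonization_rules(),
                                      biomarkers = NULL) {
  if (is.null(biomarkers)) {
    vocab <- c("biomarker", "ldl", "hdl", "total_cholesterol",
               "triglycerides", "sbp", "dbp", "glucose", "hba1c",
               "leucocytes", "alt", "ast", "alkaline_phosphatase",
               "gamma_gt", "creatinine", "creatinine_clearance",
               "urine_albumin", "uric_acid", "tsh", "free_t3", "free_t4",
               "acr", "uae", "hscrp", "haematocrit", "haemoglobin")
    biomarkers <- intersect(vocab, names(pheno))
  }
  failures <- integer(0)
  for (b in intersect(rules$log_biomarkers, biomarkers)) {
    x <- pheno[[b]]
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      x[bad] <- NA_real_
      failures[b] <- sum(bad)
    }
    pheno[[b]] <- log(x)
  }
  for (b in biomarkers) pheno[[b]] <- zscore(pheno[[b]])
  attr(pheno, "log_failures") <- failures
  pheno
}

#' Obesity indicator from BMI
#'
#' @param bmi numeric vector of BMI values (kg/m^2); non-missing values must
#'   be positive.
#' @return integer vector: 1 if BMI >= 30, 0 otherwise, NA propagated.
#' @export
derive_obesity <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("BMI must be positive")
  ifelse(is.na(bmi), NA_integer_, as.integer(bmi >= 30))
}

education_map_table <- function() {
  data.frame(
    category = education_categories(),
    years = c(1, 7, 10, 10, 13, 13, 20, 20),
    level = c("low", "low", "low", "low", "low", "low", "high", "high"),
    stringsAsFactors = FALSE)
}

#' Map education categories to years and a low/high attainment level
#'
#' Categories map to 1 (no education), 7 (primary), 10 (lower/junior
#' secondary), 13 (secondary vocational / senior general) or 20 (higher
#' vocational / university) years; attainment is "high" for the two
#' 20-year categories, "low" otherwise.
#'
#' @param category character vector of education categories.
#' @return data.frame with columns `years` and `level`.
#' @export
map_education <- function(category) {
  tab <- education_map_table()
  i <- match(category, tab$category)
  if (anyNA(i[!is.na(category)])) {
    stop("unknown education category '",
         category[!is.na(category) & is.na(i)][1],
         "'; valid categories: ",
         paste(tab$category, collapse = "; "))
  }
  data.frame(years = tab$years[i], level = tab$level[i],
             stringsAsFactors = FALSE)
}

#' Any-disease indicator for a disease group
#'
#' Logical OR over the component indicators; a missing component counts as 0
#' unless every component is missing, in which case the result is missing.
#'
#' @param pheno phenotype data.frame.
#' @param components character vector of component indicator columns.
#' @return integer vector (0/1/NA).
#' @export
derive_any_disease <- function(pheno, components) {
  if (length(components) == 0) stop("empty disease group")
  miss <- setdiff(components, names(pheno))
  if (length(miss)) stop("missing disease indicator column(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(pheno[, components, drop = FALSE])
  any1 <- rowSums(m == 1, na.rm = TRUE) > 0
  all_na <- rowSums(!is.na(m)) == 0
  ifelse(all_na, NA_integer_, as.integer(any1))
}

#' Full biomarker preparation pipeline
#'
#' Fixed order: medication adjustment, 4-SD outlier removal per biomarker,
#' log transform of listed biomarkers, z-scoring of all continuous measures.
#'
#' @param pheno phenotype data.frame.
#' @param rules a [harmonization_rules()].
#' @param biomarkers continuous biomarker columns (default as in
#'   [transform_and_standardize()]).
#' @return list with `pheno` (prepared table) and `report` (per-biomarker
#'   counts: outliers removed, log failures).
#' @export
prep_phenotypes <- function(pheno, rules = harmonization_rules(),
                            biomarkers = NULL) {
  pheno <- adjust_for_medication(pheno, rules)
  if (is.null(biomarkers)) {
    vocab <- c("biomarker", "ldl", "hdl", "total_cholesterol",
               "triglycerides", "sbp", "dbp", "glucose", "hba1c",
               "leucocytes", "hscrp", "haematocrit", "haemoglobin")
    biomarkers <- intersect(vocab, names(pheno))
  }
  n_out <- integer(length(biomarkers))
  names(n_out) <- biomarkers
  for (b in biomarkers) {
    v <- remove_outliers(pheno[[b]], rules$outlier_sd)
    n_out[b] <- attr(v, "n_removed")
    pheno[[b]] <- as.numeric(v)
  }
  pheno <- transform_and_standardize(pheno, rules, biomarkers)
  lf <- attr(pheno, "log_failures")
  report <- data.frame(biomarker = biomarkers,
                       outliers_removed = unname(n_out),
                       log_failures = unname(ifelse(
                         biomarkers %in% names(lf), lf[biomarkers], 0L)))
  list(pheno = pheno, report = report)
}
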