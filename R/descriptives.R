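#' Female percentage from sex counts
#'
#' @param n_female,n_male sex counts.
#' @param digits rounding digits (default 0, as usually printed in cohort
#'   descriptive tables).
#' @return percentage of females among females + males.
#' @export
female_percentage <- function(n_female, n_male, digits = 0) {
  stopifnot(n_female >= 0, n_male >= 0, n_female + n_male > 0)
  round(100 * n_female / (n_female + n_male), digits)
}

#' Reference cohort sex composition
#'
#' Loads the bundled sex counts of the genotyped study cohort (full sample
#' and full-sibling subsample) and computes the female percentages.
#'
#' @return data.frame with columns sample, n_female, n_male, pct_female.
#' @export
cohort_sex_composition <- function() {
  path <- system.file("extdata", "cohort_counts.tsv", package = "sibscore")
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$pct_female <- female_percentage(d$n_female, d$n_male)
  d
}

#' Descriptive summary of a phenotype table
#'
#' @param pheno phenotype data.frame with sex (1 = male, 2 = female) and
#'   age columns.
#' @return data.frame with n, n_female, n_male, pct_female, mean/SD age.
#' @export
sample_descriptives <- function(pheno) {
  nf <- sum(pheno$sex == 2, na.rm = TRUE)
  nm <- sum(pheno$sex == 1, na.rm = TRUE)
  data.frame(n = nrow(pheno), n_female = nf, n_male = nm,
             pct_female = female_percentage(nf, nm),
             age_mean = mean(pheno$age, na.rm = TRUE),
             age_sd = stats::sd(pheno$age, na.rm = TRUE))
}
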