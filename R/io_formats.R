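## Readers / writers for the external formats: summary-statistics TSV,
## genotypes as VCF (DS/GT) or dosage TSV, whitespace pedigree, phenotype
## TSV and the results TSV. All readers fail loudly; none returns a silently
## wrong value.

default_sumstats_map <- function() {
  c(id = "SNP", chrom = "CHR", pos = "BP", effect_allele = "A1",
    other_allele = "A2", weight = "BETA", se = "SE", p = "P",
    info = "INFO", maf = "FRQ")
}

#' Read GWAS summary statistics
#'
#' @param path TSV file with a header.
#' @param column_map named character vector mapping internal field names
#'   (id, chrom, pos, effect_allele, other_allele, weight, se, p, maf, info)
#'   to file column names; defaults to the SNP/CHR/BP/A1/A2/BETA/SE/P/INFO/FRQ
#'   dialect.
#' @return `summary_stats` data.frame; rows whose numeric fields fail to
#'   parse are dropped, with the count in attribute `n_dropped` and a
#'   message.
#' @export
read_sumstats <- function(path, column_map = default_sumstats_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0) stop("empty summary-statistics file: ", path)
  miss <- setdiff(unname(column_map), names(raw))
  if (length(miss)) {
    stop("summary-statistics file missing column(s): ",
         paste(miss, collapse = ", "))
  }
  out <- data.frame(id = raw[[column_map["id"]]],
                    chrom = raw[[column_map["chrom"]]],
                    stringsAsFactors = FALSE)
  num_fields <- c("pos", "weight", "se", "p", "maf", "info")
  for (f in c("effect_allele", "other_allele")) {
    out[[f]] <- raw[[column_map[f]]]
  }
  suppressWarnings(for (f in num_fields) {
    out[[f]] <- as.numeric(raw[[column_map[f]]])
  })
  bad <- rowSums(is.na(out[num_fields])) > 0
  if (any(bad)) {
    message("read_sumstats: dropped ", sum(bad),
            " row(s) with unparseable numeric fields")
  }
  out <- out[!bad, c("id", "chrom", "pos", "effect_allele", "other_allele",
                     "weight", "se", "p", "maf", "info")]
  if (anyDuplicated(out$id)) {
    stop("duplicated variant id in summary statistics: ",
         out$id[duplicated(out$id)][1])
  }
  attr(out, "n_dropped") <- sum(bad)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write summary statistics in the SNP/CHR/BP/... dialect
#' @param sumstats `summary_stats` data.frame.
#' @param path output path.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(SNP = sumstats$id, CHR = sumstats$chrom,
                    BP = sumstats$pos, A1 = sumstats$effect_allele,
                    A2 = sumstats$other_allele,
                    BETA = num17(sumstats$weight), SE = num17(sumstats$se),
                    P = num17(sumstats$p), INFO = num17(sumstats$info),
                    FRQ = num17(sumstats$maf))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

num17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Read genotypes from a VCF (DS preferred, GT fallback)
#'
#' Dosage is taken from the DS FORMAT field when present, otherwise from the
#' ALT-allele count of GT. The counted allele is ALT. Multi-allelic records
#' are dropped (count in attribute `n_multiallelic`).
#'
#' @param path VCF 4.x file (plain text or gzipped).
#' @return a [genotype_set()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (is.null(dim(fm))) {      # single record: vcfR returns a bare vector
    fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
  }
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) NA_real_ else
          sum(a != "0")
      }, numeric(1))
    })
    ds <- matrix(ds, nrow = nrow(fix))
  } else {
    stop("VCF has neither DS nor GT in FORMAT")
  }
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         counted_allele = fix$ALT, other_allele = fix$REF,
                         stringsAsFactors = FALSE)
  g <- genotype_set(t(ds), variants, colnames(v@gt)[-1])
  attr(g, "n_multiallelic") <- n_multi
  g
}

#' Write genotypes as VCF 4.2 with a DS FORMAT field
#' @param genotypes a [genotype_set()].
#' @param path output path.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                      "Description=\"Dosage of the ALT allele\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", genotypes$sample_ids),
                     collapse = "\t")), con)
  ds <- t(genotypes$dosage)
  body <- vapply(seq_len(nrow(v)), function(i) {
    vals <- ifelse(is.na(ds[i, ]), ".", formatC(ds[i, ], format = "g",
                                                digits = 15))
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$other_allele[i],
            v$counted_allele[i], ".", "PASS", ".", "DS", vals),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a dosage TSV
#'
#' Dialect: header columns id, chrom, pos, counted_allele, other_allele,
#' then one column per sample; one row per variant.
#'
#' @param path TSV file.
#' @return a [genotype_set()].
#' @export
read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("id", "chrom", "pos", "counted_allele", "other_allele")
  miss <- setdiff(meta, names(d))
  if (length(miss)) stop("dosage TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  samp <- setdiff(names(d), meta)
  if (length(samp) == 0) stop("dosage TSV has no sample columns")
  dm <- t(as.matrix(d[, samp, drop = FALSE]))
  genotype_set(dm, d[, meta], samp)
}

#' Write genotypes as a dosage TSV
#' @param genotypes a [genotype_set()].
#' @param path output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  v <- genotypes$variants[, c("id", "chrom", "pos", "counted_allele",
                              "other_allele")]
  m <- as.data.frame(t(genotypes$dosage))
  names(m) <- genotypes$sample_ids
  utils::write.table(cbind(v, m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a whitespace-delimited pedigree (FID IID PAT MAT SEX)
#'
#' Missing parents are coded "0". Rows with exactly one known parent are
#' flagged in attribute `half_info` (they can never enter a full-sibling
#' stratum) with a warning.
#'
#' @param path pedigree file, with or without a header line.
#' @return data.frame with columns family_id, individual_id, father_id,
#'   mother_id, sex.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("FID|family", first, ignore.case = TRUE)
  d <- utils::read.table(path, header = has_header,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(d) < 5) stop("pedigree needs 5 columns: FID IID PAT MAT SEX")
  names(d)[1:5] <- c("family_id", "individual_id", "father_id",
                     "mother_id", "sex")
  d <- d[, 1:5]
  d$sex <- as.integer(d$sex)
  if (anyDuplicated(d$individual_id)) {
    stop("duplicated individual id in pedigree: ",
         d$individual_id[duplicated(d$individual_id)][1])
  }
  half <- xor(d$father_id == "0", d$mother_id == "0")
  if (any(half)) {
    warning(sum(half), " pedigree record(s) with exactly one known parent",
            call. = FALSE)
  }
  attr(d, "half_info") <- d$individual_id[half]
  d
}

#' Write a pedigree (FID IID PAT MAT SEX, whitespace-delimited)
#' @param pedigree pedigree data.frame.
#' @param path output path.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(
    pedigree[, c("family_id", "individual_id", "father_id", "mother_id",
                 "sex")],
    path, sep = " ", quote = FALSE, row.names = FALSE,
    col.names = c("FID", "IID", "PAT", "MAT", "SEX"))
  invisible(path)
}

#' Read a phenotype / covariate table
#'
#' @param path TSV with header.
#' @param schema character vector of required column names.
#' @return data.frame.
#' @export
read_phenotypes <- function(path,
                            schema = c("family_id", "individual_id",
                                       "age", "sex")) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(schema, names(d))
  if (length(miss)) {
    stop("phenotype file missing column(s): ", paste(miss, collapse = ", "))
  }
  d
}

#' Write a phenotype table
#' @param pheno data.frame.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

results_columns <- function() {
  c("outcome", "model", "n", "estimate", "se", "ci_low", "ci_high",
    "p", "p_fdr", "r2_delta")
}

#' Write an association results table
#'
#' Numeric columns are written with 17 significant digits so that a
#' write-read round trip preserves values to better than 1e-12.
#'
#' @param results data.frame with the standard result columns (outcome,
#'   model, n, estimate, se, ci_low, ci_high, p, p_fdr, r2_delta).
#' @param path output path.
#' @export
write_results <- function(results, path) {
  cols <- results_columns()
  miss <- setdiff(cols, names(results))
  if (length(miss)) stop("results table missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- results[, cols]
  for (cc in cols[-(1:2)]) out[[cc]] <- num17(results[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an association results table written by [write_results()]
#' @param path TSV path.
#' @return data.frame with typed columns.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(results_columns(), names(d))
  if (length(miss)) stop("results file missing column(s): ",
                         paste(miss, collapse = ", "))
  for (cc in setdiff(results_columns(), c("outcome", "model"))) {
    d[[cc]] <- as.numeric(d[[cc]])
  }
  d
}

#' Write the truth ledger of a simulated cohort
#' @param truth `truth_ledger` from [build_truth()].
#' @param path output path (TSV; per-sample block then a variant block
#'   written alongside as `<path>.variants`).
#' @export
write_truth <- function(truth, path) {
  per_sample <- data.frame(individual_id = names(truth$pgs_true),
                           family_id = unname(truth$family_id),
                           pgs_true = num17(unname(truth$pgs_true)),
                           midparent_pgs = num17(unname(truth$midparent_pgs)))
  utils::write.table(per_sample, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  v <- truth$variants[, c("id", "chrom", "pos", "true_weight")]
  v$true_weight <- num17(v$true_weight)
  utils::write.table(v, paste0(path, ".variants"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
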