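#' Genotype dosage container
#'
#' A light container holding a sample-by-variant dosage matrix together with
#' variant metadata. Dosages count copies of the counted allele and may be
#' fractional for imputed data.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns;
#'   values in \[0, 2\] or NA.
#' @param variants data.frame with columns `id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele` (one row per dosage column).
#' @param sample_ids character vector, one per dosage row.
#' @param haplotypes optional list of two 0/1 integer matrices of the same
#'   shape as `dosage` (phased alleles; kept by the simulator so that
#'   transmission can act on haplotypes).
#' @return an object of class `genotype_set`.
#' @export
genotype_set <- function(dosage, variants, sample_ids, haplotypes = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(variants) == ncol(dosage),
            length(sample_ids) == nrow(dosage))
  need <- c("id", "chrom", "pos", "counted_allele", "other_allele")
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    stop("variant metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant ids in genotype set: ",
         variants$id[duplicated(variants$id)][1])
  }
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  rownames(dosage) <- sample_ids
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage,
                 variants = as.data.frame(variants),
                 sample_ids = as.character(sample_ids),
                 haplotypes = haplotypes),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = " "), "\n")
  cat("  missing dosages:", sum(is.na(x$dosage)), "\n")
  invisible(x)
}

#' @export
dim.genotype_set <- function(x) dim(x$dosage)

## subset by sample and/or variant index
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(g$sample_ids) else samples
  vi <- if (is.null(variants)) seq_len(nrow(g$variants)) else variants
  hap <- if (!is.null(g$haplotypes)) {
    lapply(g$haplotypes, function(h) h[si, vi, drop = FALSE])
  }
  genotype_set(g$dosage[si, vi, drop = FALSE],
               g$variants[vi, , drop = FALSE],
               g$sample_ids[si], haplotypes = hap)
}
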