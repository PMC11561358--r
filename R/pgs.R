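#' Default p-value thresholds for multi-threshold scoring
#' @export
pgs_thresholds <- function() {
  c(5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)
}

#' Quality-control filter for GWAS summary statistics
#'
#' Removes strand-ambiguous variants (allele pair A/T or C/G) and keeps only
#' variants with MAF > 0.01 and INFO > 0.8 (strict inequalities). Removal
#' counts per rule are attached as attribute `qc_counts`.
#'
#' @param sumstats a summary-statistics data.frame (columns `id`,
#'   `effect_allele`, `other_allele`, `maf`, `info`, ...).
#' @return the filtered data.frame, with attribute `qc_counts`.
#' @export
qc_filter <- function(sumstats) {
  pair <- paste(sumstats$effect_allele, sumstats$other_allele)
  ambiguous <- pair %in% c("A T", "T A", "C G", "G C")
  low_maf <- !ambiguous & sumstats$maf <= 0.01
  low_info <- !ambiguous & !low_maf & sumstats$info <= 0.8
  keep <- !(ambiguous | low_maf | low_info)
  out <- sumstats[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no variants survive QC", call. = FALSE)
  attr(out, "qc_counts") <- c(ambiguous = sum(ambiguous),
                              maf = sum(low_maf),
                              info = sum(low_info))
  out
}

#' Harmonize summary-statistic weights to the genotype counted allele
#'
#' Intersects on variant id. When the effect allele equals the genotype's
#' counted allele the weight is kept; when it equals the other allele the
#' weight is negated; any other allele combination is dropped (count in
#' attribute `n_mismatch`).
#'
#' @param sumstats QC-passed summary statistics.
#' @param genotypes a [genotype_set()].
#' @return data.frame with columns id, chrom, pos, weight (aligned), p.
#' @export
harmonize <- function(sumstats, genotypes) {
  gv <- genotypes$variants
  idx <- match(sumstats$id, gv$id)
  present <- !is.na(idx)
  ss <- sumstats[present, , drop = FALSE]
  gv <- gv[idx[present], , drop = FALSE]
  if (nrow(ss) == 0) stop("no overlapping variants between summary ",
                          "statistics and genotypes")
  same <- ss$effect_allele == gv$counted_allele &
    ss$other_allele == gv$other_allele
  flip <- ss$effect_allele == gv$other_allele &
    ss$other_allele == gv$counted_allele
  keep <- same | flip
  out <- data.frame(id = ss$id[keep],
                    chrom = gv$chrom[keep], pos = gv$pos[keep],
                    weight = ifelse(flip[keep], -ss$weight[keep],
                                    ss$weight[keep]),
                    p = ss$p[keep], stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("no variants left after allele harmonization")
  attr(out, "n_mismatch") <- sum(!keep)
  out
}

#' Greedy LD clumping
#'
#' Repeatedly selects the remaining variant with the smallest p-value as
#' index and removes all remaining variants on the same chromosome within
#' `window_bp` whose squared Pearson correlation of reference dosages with
#' the index exceeds `r2_max`. Ties on p are broken by (chrom, pos, id), so
#' the result does not depend on input row order.
#'
#' @param sumstats data.frame with columns id, chrom, pos, p (typically the
#'   harmonized weight table).
#' @param reference [genotype_set()] providing dosages for the r2
#'   computation (an LD reference panel; e.g. the founder subset).
#' @param r2_max r-squared threshold above which neighbours are removed.
#' @param window_bp window half-width: neighbours with
#'   `|pos_i - pos_j| <= window_bp` are considered.
#' @param missing_reference "drop" (default; drop candidates absent from the
#'   reference, with a warning) or "error".
#' @return character vector of retained variant ids, in selection order.
#' @export
ld_clump <- function(sumstats, reference, r2_max = 0.1,
                     window_bp = 250000, missing_reference = c("drop",
                                                               "error")) {
  missing_reference <- match.arg(missing_reference)
  ridx <- match(sumstats$id, reference$variants$id)
  if (anyNA(ridx)) {
    if (missing_reference == "error") {
      stop("variant(s) absent from LD reference: ",
           sumstats$id[is.na(ridx)][1])
    }
    warning(sum(is.na(ridx)), " variant(s) absent from LD reference dropped",
            call. = FALSE)
  }
  keep <- !is.na(ridx)
  ss <- sumstats[keep, , drop = FALSE]
  ridx <- ridx[keep]
  if (nrow(ss) == 0) return(character(0))
  ord <- order(ss$p, ss$chrom, ss$pos, ss$id)
  ss <- ss[ord, , drop = FALSE]
  ridx <- ridx[ord]
  D <- reference$dosage
  alive <- rep(TRUE, nrow(ss))
  retained <- character(0)
  for (i in seq_len(nrow(ss))) {
    if (!alive[i]) next
    retained <- c(retained, ss$id[i])
    alive[i] <- FALSE
    cand <- which(alive & ss$chrom == ss$chrom[i] &
                    abs(ss$pos - ss$pos[i]) <= window_bp)
    if (length(cand)) {
      r <- suppressWarnings(
        stats::cor(D[, ridx[i]], D[, ridx[cand], drop = FALSE],
                   use = "pairwise.complete.obs"))
      r2 <- as.vector(r)^2
      r2[is.na(r2)] <- 0
      alive[cand[r2 > r2_max]] <- FALSE
    }
  }
  retained
}

#' Multi-threshold polygenic scoring
#'
#' For every p-value threshold, the raw score is the dosage-weighted sum over
#' variants with `p <= threshold`; each raw column is then z-scored across
#' samples. Missing dosages are mean-imputed per variant before scoring.
#'
#' @param genotypes a [genotype_set()].
#' @param weights harmonized weight table (id, weight, p), typically
#'   restricted to LD-clumped variants.
#' @param thresholds ordered p-value cutoffs (default [pgs_thresholds()]).
#' @return object of class `threshold_scores`: list with `thresholds`, `raw`
#'   and `z` matrices (samples x thresholds) and `n_variants` per threshold.
#' @export
pgs_score <- function(genotypes, weights, thresholds = pgs_thresholds()) {
  idx <- match(weights$id, genotypes$variants$id)
  if (anyNA(idx)) stop("weight table contains variants absent from genotypes")
  D <- genotypes$dosage[, idx, drop = FALSE]
  if (anyNA(D)) {
    cm <- colMeans(D, na.rm = TRUE)
    for (j in which(colSums(is.na(D)) > 0)) {
      D[is.na(D[, j]), j] <- cm[j]
    }
  }
  n <- nrow(D)
  raw <- matrix(0, n, length(thresholds))
  nv <- integer(length(thresholds))
  for (t in seq_along(thresholds)) {
    sel <- weights$p <= thresholds[t]
    nv[t] <- sum(sel)
    if (nv[t] > 0) {
      raw[, t] <- D[, sel, drop = FALSE] %*% weights$weight[sel]
    }
  }
  z <- apply(raw, 2, zscore)
  empty <- nv == 0 | apply(raw, 2, stats::sd) == 0
  if (any(nv == 0)) {
    warning("threshold(s) with zero variants: ",
            paste(format(thresholds[nv == 0]), collapse = ", "),
            call. = FALSE)
  }
  z[, empty] <- 0
  dimnames(raw) <- dimnames(z) <-
    list(genotypes$sample_ids, paste0("pT_", format(thresholds)))
  structure(list(thresholds = thresholds, raw = raw, z = z,
                 n_variants = nv),
            class = "threshold_scores")
}

#' Aggregate threshold scores into a final PGS (PGS-PCA)
#'
#' Takes the first principal component of the z-scored per-threshold scores,
#' sign-aligned to correlate positively with the across-threshold mean, so
#' that a higher final score always means higher polygenic load.
#'
#' @param scores a `threshold_scores` object.
#' @return object of class `pgs_result`: list with `score` (named, mean 0),
#'   `loadings` per threshold and `var_explained` by the first component.
#' @export
pgs_pca <- function(scores) {
  X <- scores$z
  if (nrow(X) < 2) stop("PGS-PCA needs at least 2 samples")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  s1 <- pc$x[, 1]
  load <- pc$rotation[, 1]
  ref <- rowMeans(X)
  al <- if (stats::sd(ref) > 0 && stats::sd(s1) > 0) {
    stats::cor(s1, ref)
  } else sum(load)
  if (is.na(al)) al <- sum(load)
  if (al < 0) {
    s1 <- -s1
    load <- -load
  }
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  structure(list(score = stats::setNames(s1, rownames(X)),
                 loadings = load, var_explained = ve),
            class = "pgs_result")
}

#' @export
print.pgs_result <- function(x, ...) {
  cat("pgs_result:", length(x$score), "samples; first PC explains",
      sprintf("%.1f%%", 100 * x$var_explained),
      "of threshold-score variance\n")
  invisible(x)
}

#' Genotype principal components
#'
#' Top-k principal components of the mean-centered dosage matrix, each
#' z-scored, for use as ancestry covariates.
#'
#' @param genotypes a [genotype_set()].
#' @param k number of components (default 8).
#' @return numeric matrix (samples x k), columns PC1..PCk.
#' @export
compute_genotype_pcs <- function(genotypes, k = 8) {
  n <- length(genotypes$sample_ids)
  if (k == 0) {
    return(matrix(numeric(0), n, 0,
                  dimnames = list(genotypes$sample_ids, NULL)))
  }
  if (n < k + 1) stop("need at least k + 1 samples for ", k, " PCs")
  D <- genotypes$dosage
  if (anyNA(D)) {
    cm <- colMeans(D, na.rm = TRUE)
    for (j in which(colSums(is.na(D)) > 0)) D[is.na(D[, j]), j] <- cm[j]
  }
  kmax <- min(n - 1, ncol(D))
  if (k > kmax) {
    warning("rank supports only ", kmax, " PCs", call. = FALSE)
    k <- kmax
  }
  pc <- stats::prcomp(D, center = TRUE, scale. = FALSE, rank. = k)
  ## stabilize the arbitrary PCA sign: largest-magnitude loading positive
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) sc[, j] <- -sc[, j]
  }
  out <- apply(sc, 2, zscore)
  out <- matrix(out, nrow = n)
  dimnames(out) <- list(genotypes$sample_ids, paste0("PC", seq_len(k)))
  out
}

#' Full PGS construction pipeline
#'
#' QC filter -> allele harmonization -> LD clumping -> multi-threshold
#' scoring -> PGS-PCA aggregation.
#'
#' @param sumstats summary statistics data.frame.
#' @param genotypes target [genotype_set()] to score.
#' @param reference LD reference panel (default: the target genotypes).
#' @param r2_max,window_bp clumping parameters.
#' @param thresholds p-value cutoffs.
#' @return list with `pgs` (named final scores), `result` (`pgs_result`),
#'   `scores` (`threshold_scores`), `clumped` ids, `weights` and a `qc`
#'   report.
#' @export
pgs_pipeline <- function(sumstats, genotypes, reference = genotypes,
                         r2_max = 0.1, window_bp = 250000,
                         thresholds = pgs_thresholds()) {
  qcd <- qc_filter(sumstats)
  w <- harmonize(qcd, genotypes)
  kept <- ld_clump(w, reference, r2_max = r2_max, window_bp = window_bp)
  wk <- w[w$id %in% kept, , drop = FALSE]
  sc <- pgs_score(genotypes, wk, thresholds)
  res <- pgs_pca(sc)
  qc <- data.frame(rule = c(names(attr(qcd, "qc_counts")),
                            "allele_mismatch", "clump_removed"),
                   removed = c(unname(attr(qcd, "qc_counts")),
                               attr(w, "n_mismatch"),
                               nrow(w) - length(kept)))
  list(pgs = res$score, result = res, scores = sc, clumped = kept,
       weights = wk, qc = qc)
}
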