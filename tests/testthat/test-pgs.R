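make_ss <- function(id, a1, a2, maf = 0.3, info = 0.95, p = 0.01,
                    weight = 0.1, chrom = "1", pos = NULL) {
  data.frame(id = id, chrom = chrom,
             pos = pos %||% (seq_along(id) * 1000L),
             effect_allele = a1, other_allele = a2,
             weight = weight, se = 0.02, p = p, maf = maf, info = info,
             stringsAsFactors = FALSE)
}

test_that("QC removes ambiguous, low-MAF and low-INFO variants strictly", {
  ss <- make_ss(c("a", "b", "c", "d", "e"),
                a1 = c("A", "G", "G", "G", "C"),
                a2 = c("T", "A", "A", "A", "G"),
                maf = c(0.3, 0.005, 0.05, 0.01, 0.3),
                info = c(0.95, 0.9, 0.9, 0.9, 0.95))
  out <- qc_filter(ss)
  expect_identical(out$id, "c")   # A/T and C/G ambiguous; MAF 0.005 and
                                  # boundary MAF 0.01 removed (strict >)
  expect_equal(unname(attr(out, "qc_counts")),
               c(2L, 2L, 0L))
  ## INFO boundary 0.8 is also removed under the strict inequality
  ss2 <- make_ss("f", "G", "A", maf = 0.3, info = 0.8)
  expect_warning(out2 <- qc_filter(ss2), "no variants")
  expect_equal(nrow(out2), 0)
})

test_that("harmonization aligns weights to the counted allele", {
  g <- make_geno(matrix(c(0, 1, 2, 1), 2, 2), ids = c("v1", "v2"))
  g$variants$counted_allele <- c("A", "G")
  g$variants$other_allele <- c("G", "A")
  ss <- make_ss(c("v1", "v2", "v3"), a1 = c("A", "A", "A"),
                a2 = c("G", "G", "G"), weight = c(0.5, 0.5, 0.5))
  h <- harmonize(ss, g)
  expect_equal(h$weight, c(0.5, -0.5))  # v2 counted allele is the "other"
  ## mismatched allele pair dropped with a count
  g2 <- make_geno(matrix(0, 2, 1), ids = "v1")
  g2$variants$counted_allele <- "C"
  g2$variants$other_allele <- "T"
  expect_error(harmonize(make_ss("v1", "A", "G"), g2),
               "harmonization")
  g3 <- make_geno(matrix(0, 2, 2), ids = c("v1", "v2"))
  g3$variants$counted_allele <- c("A", "C")
  g3$variants$other_allele <- c("G", "T")
  h3 <- harmonize(make_ss(c("v1", "v2"), "A", "G"), g3)
  expect_equal(attr(h3, "n_mismatch"), 1L)
  expect_error(harmonize(make_ss("zz", "A", "G"), g3), "overlap")
})

test_that("clumping respects the window and matches the brute-force greedy", {
  ## identical dosages 300 kb apart: outside the window, both kept
  set.seed(1)
  x <- rbinom(200, 2, 0.3)
  g <- make_geno(cbind(x, x), pos = c(1L, 300001L), ids = c("v1", "v2"))
  tab <- make_ss(c("v1", "v2"), "A", "G", p = c(1e-8, 1e-4),
                 pos = c(1L, 300001L))
  expect_setequal(ld_clump(tab, g), c("v1", "v2"))
  ## inside the window the weaker one is removed
  g2 <- make_geno(cbind(x, x), pos = c(1L, 200001L), ids = c("v1", "v2"))
  tab2 <- make_ss(c("v1", "v2"), "A", "G", p = c(1e-8, 1e-4),
                  pos = c(1L, 200001L))
  expect_identical(ld_clump(tab2, g2), "v1")

  ## 6-variant instances against the from-scratch greedy oracle
  for (seed in 1:5) {
    set.seed(seed)
    base <- matrix(rbinom(300 * 3, 1, 0.4), 300, 3)
    noise <- function() rbinom(300, 1, 0.15)
    D <- cbind(base[, 1], (base[, 1] + noise()) %% 2, base[, 2],
               (base[, 2] + noise()) %% 2, base[, 3], noise())
    pos <- c(1e4, 2e4, 5e4, 6e4, 9e4, 3e5)
    ids <- paste0("v", 1:6)
    g6 <- make_geno(D, pos = as.integer(pos), ids = ids)
    tab6 <- make_ss(ids, "A", "G", p = runif(6), pos = as.integer(pos))
    dose_by_id <- g6$dosage
    expect_identical(sort(ld_clump(tab6, g6)),
                     sort(clump_oracle(tab6, dose_by_id, 0.1, 250000)))
    ## row order must not matter
    perm <- sample(6)
    expect_setequal(ld_clump(tab6[perm, ], g6), ld_clump(tab6, g6))
  }

  ## candidate absent from the reference: warn and drop, or error
  tab_extra <- make_ss(c("v1", "zz"), "A", "G", pos = c(1L, 5000L))
  expect_warning(kept <- ld_clump(tab_extra, g), "absent")
  expect_identical(kept, "v1")
  expect_error(ld_clump(tab_extra, g, missing_reference = "error"), "zz")
})

test_that("threshold scoring is the weighted dosage sum with z-scoring", {
  g <- make_geno(matrix(c(2, 0, 1, 1), 2, 2), ids = c("v1", "v2"))
  w <- data.frame(id = c("v1", "v2"), weight = c(0.1, -0.2),
                  p = c(1e-9, 1e-9))
  sc <- pgs_score(g, w, thresholds = 1)
  expect_equal(unname(sc$raw[1, 1]), 2 * 0.1 + 1 * (-0.2))  # = 0
  expect_equal(unname(sc$raw[2, 1]), 0 * 0.1 + 1 * (-0.2))

  ## doubling dosages doubles raw scores, leaves z-scores unchanged
  g1 <- make_geno(matrix(c(1, 0, 1, 0, 0, 1), 3, 2), ids = c("v1", "v2"))
  g2 <- g1; g2$dosage <- g1$dosage * 2
  s1 <- pgs_score(g1, w, thresholds = 1)
  s2 <- pgs_score(g2, w, thresholds = 1)
  expect_equal(s2$raw, 2 * s1$raw, ignore_attr = TRUE)
  expect_equal(s2$z, s1$z, tolerance = 1e-12)

  ## variant counts weakly increase with the threshold
  cfg <- sim_config(n_families = 100, n_variants = 200,
                    disease_prevalence = c(metabolic_disease = 0.3),
                    seed = 31)
  co <- simulate_cohort(cfg)
  h <- harmonize(qc_filter(co$sumstats), co$genotypes)
  sc2 <- pgs_score(co$genotypes, h)
  expect_true(all(diff(sc2$n_variants) >= 0))
  ## z-columns have mean 0 and SD 1
  nz <- sc2$n_variants > 0
  expect_true(all(abs(colMeans(sc2$z[, nz])) < 1e-9))
  expect_true(all(abs(apply(sc2$z[, nz], 2, sd) - 1) < 1e-9))

  ## an empty threshold gives an all-zero column and a warning
  w_late <- data.frame(id = c("v1", "v2"), weight = c(0.1, -0.2),
                       p = c(0.5, 0.6))
  expect_warning(s3 <- pgs_score(g1, w_late, thresholds = c(1e-8, 1)),
                 "zero variants")
  expect_true(all(s3$z[, 1] == 0))
})

test_that("PGS-PCA matches an eigendecomposition and handles degeneracy", {
  ## all columns identical: final score is that column (r = 1), 100% var
  set.seed(41)
  col <- as.vector(scale(rnorm(100)))
  sc <- structure(list(z = matrix(col, 100, 11), thresholds = rep(1, 11),
                       n_variants = rep(5L, 11)),
                  class = "threshold_scores")
  dimnames(sc$z) <- list(sprintf("S%03d", 1:100), NULL)
  r <- pgs_pca(sc)
  expect_equal(abs(stats::cor(r$score, col)), 1, tolerance = 1e-12)
  expect_equal(r$var_explained, 1, tolerance = 1e-12)
  expect_gte(stats::cor(r$score, rowMeans(sc$z)), 0)

  ## two orthogonal equal-variance columns: 50% variance explained
  n <- 1000
  a <- as.vector(scale(rnorm(n))); b <- as.vector(scale(residuals(lm(rnorm(n) ~ a))))
  sc2 <- structure(list(z = cbind(a, b), thresholds = c(0.5, 1),
                        n_variants = c(3L, 4L)),
                   class = "threshold_scores")
  dimnames(sc2$z) <- list(sprintf("S%04d", 1:n), NULL)
  r2 <- pgs_pca(sc2)
  expect_equal(r2$var_explained, 0.5, tolerance = 1e-6)

  ## random instance against the brute-force eigendecomposition
  set.seed(42)
  Z <- matrix(rnorm(200 * 11), 200, 11)
  Z <- Z %*% chol(0.5 + 0.5 * diag(11))  # correlated columns
  Z <- apply(Z, 2, scale)
  sc3 <- structure(list(z = Z, thresholds = pgs_thresholds(),
                        n_variants = rep(10L, 11)),
                   class = "threshold_scores")
  dimnames(sc3$z) <- list(sprintf("S%04d", 1:200), NULL)
  r3 <- pgs_pca(sc3)
  ev <- eigen(stats::cor(Z))          # oracle: correlation-matrix eigen
  oracle <- as.vector(scale(Z, scale = FALSE) %*% ev$vectors[, 1])
  expect_gt(abs(stats::cor(r3$score, oracle)), 0.999999)
  expect_equal(r3$var_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-9)
  expect_equal(mean(r3$score), 0, tolerance = 1e-12)
  expect_error(pgs_pca(structure(list(z = Z[1, , drop = FALSE]),
                                 class = "threshold_scores")),
               "2 samples")
})

test_that("genotype PCs separate subpopulations and behave under permutation", {
  cfg <- sim_config(n_families = 300, n_variants = 150, n_subpops = 2,
                    freq_divergence = 0.4,
                    disease_prevalence = c(metabolic_disease = 0.3),
                    seed = 51)
  f <- simulate_founders(cfg)
  pcs <- compute_genotype_pcs(f$genotypes, k = 2)
  sub <- f$subpop[f$pedigree$family_id]
  expect_gt(abs(stats::cor(pcs[, 1], as.numeric(sub))), 0.9)

  perm <- sample(nrow(pcs))
  gp <- subset_genotypes(f$genotypes, samples = perm)
  pcs_p <- compute_genotype_pcs(gp, k = 2)
  expect_equal(unname(pcs_p), unname(pcs[perm, ]), tolerance = 1e-8)

  expect_equal(ncol(compute_genotype_pcs(f$genotypes, k = 0)), 0)
  small <- subset_genotypes(f$genotypes, samples = 1:5, variants = 1:3)
  expect_warning(p2 <- compute_genotype_pcs(small, k = 4), "rank")
  expect_lte(ncol(p2), 3)
})

test_that("the score pipeline is deterministic and recovers the true PGS", {
  cfg <- sim_config(n_families = 500, n_variants = 300,
                    within_block_rho = 0, gwas_se = 1e-4,
                    fraction_ambiguous = 0, fraction_low_maf = 0,
                    fraction_low_info = 0,
                    disease_prevalence = c(metabolic_disease = 0.3),
                    seed = 61)
  co <- simulate_cohort(cfg)
  p1 <- pgs_pipeline(co$sumstats, co$genotypes,
                     reference = co$founders$genotypes)
  p2 <- pgs_pipeline(co$sumstats, co$genotypes,
                     reference = co$founders$genotypes)
  expect_equal(p1$pgs, p2$pgs, tolerance = 1e-12)
  ## near-noiseless weights, no LD, no QC losses: the constructed score
  ## converges on the true standardized PGS
  expect_gt(stats::cor(p1$pgs[co$genotypes$sample_ids],
                       co$truth$pgs_true), 0.99)
})
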