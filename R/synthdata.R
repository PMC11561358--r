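#' Simulation configuration for the family-genotype generator
#'
#' Bundles every knob of the generative model: family structure, block-LD
#' genotypes, the causal model linking a child's own polygenic score (direct
#' effect) and the midparent score (genetic nurture) to outcomes, shared
#' family environment, optional population stratification and assortative
#' mating, liability-threshold diseases, medication flags and the sampling
#' noise of the simulated GWAS.
#'
#' The defaults encode the study conditions used throughout the package's
#' tests: a direct effect of 0.2 SD and a nurture effect of 0.3 SD per SD of
#' (mid)parent score, a shared-environment variance of 0.1, and residual
#' noise chosen so the continuous outcome has unit variance under random
#' mating.
#'
#' @param n_families number of nuclear families.
#' @param sibs_per_family full siblings per family (>= 1).
#' @param n_variants number of biallelic variants.
#' @param block_size variants per LD block (last block may be shorter).
#' @param within_block_rho lag-1 correlation of the latent AR(1) process
#'   generating haplotype alleles within a block, in \[0, 1).
#' @param allele_freq_range range the per-variant allele frequency is drawn
#'   from, both endpoints in (0, 1).
#' @param beta_direct effect of the child's own standardized true PGS on the
#'   continuous outcome (per-SD units).
#' @param beta_nurture effect of the midparent standardized PGS (genetic
#'   nurture acting through the rearing environment).
#' @param var_shared_env variance of the family-level environment term.
#' @param var_noise residual variance of the continuous outcome.
#' @param n_subpops 1 or 2 ancestry strata.
#' @param freq_divergence allele-frequency offset between the two subpops
#'   (applied as +/- freq_divergence/2).
#' @param freq_divergence_aligned fraction of variants whose divergence
#'   direction follows the sign of the true weight (risk alleles more
#'   frequent in subpop 2), making the subpop mean PGS systematically
#'   higher there; the remainder diverge with random direction. 0 gives
#'   purely random divergence.
#' @param subpop_env_shift mean environment offset of subpop 2 relative to
#'   subpop 1 (creates stratification confounding when nonzero).
#' @param mate_corr spousal correlation of the liability proxy (the parents'
#'   standardized true PGS) under assortative mating, in \[0, 1).
#' @param disease_prevalence named numeric vector of liability-threshold
#'   prevalences for the binary outcomes.
#' @param med_flag_quantile samples above this quantile of the relevant raw
#'   biomarker receive the corresponding medication flag.
#' @param gwas_se sampling standard error of the simulated GWAS log-odds
#'   estimates.
#' @param weight_sd SD of the per-variant true log-odds weights.
#' @param fraction_ambiguous fraction of variants given strand-ambiguous
#'   allele pairs (A/T or C/G).
#' @param fraction_low_maf fraction of variants reported with MAF < 1\% in the
#'   summary statistics.
#' @param fraction_low_info fraction reported with INFO < 0.8.
#' @param fraction_flipped fraction of summary-stat rows whose effect allele
#'   is reported as the genotype's other allele (weight sign flipped
#'   accordingly; exercises harmonization).
#' @param seed master RNG seed; every stochastic stage derives a named
#'   substream from it via [substream_seed()].
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_families = 2000,
                       sibs_per_family = 2,
                       n_variants = 2000,
                       block_size = 10,
                       within_block_rho = 0.4,
                       allele_freq_range = c(0.05, 0.5),
                       beta_direct = 0.2,
                       beta_nurture = 0.3,
                       var_shared_env = 0.1,
                       var_noise = 0.755,
                       n_subpops = 1,
                       freq_divergence = 0,
                       freq_divergence_aligned = 0,
                       subpop_env_shift = 0,
                       mate_corr = 0,
                       disease_prevalence = c(metabolic_disease = 0.30,
                                              cardiovascular_disease = 0.05),
                       med_flag_quantile = 0.9,
                       gwas_se = 0.01,
                       weight_sd = 0.05,
                       fraction_ambiguous = 0.05,
                       fraction_low_maf = 0.02,
                       fraction_low_info = 0.02,
                       fraction_flipped = 0.05,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_families >= 1, sibs_per_family >= 1, n_variants >= 1,
              block_size >= 1)
    if (within_block_rho < 0 || within_block_rho >= 1) {
      stop("within_block_rho must lie in [0, 1)")
    }
    if (any(allele_freq_range <= 0) || any(allele_freq_range >= 1)) {
      stop("allele_freq_range endpoints must lie in (0, 1)")
    }
    if (var_shared_env < 0 || var_noise < 0) stop("variances must be >= 0")
    if (!n_subpops %in% c(1L, 2L)) {
      stop("n_subpops must be 1 or 2 (more subpopulations are unsupported)")
    }
    if (mate_corr < 0 || mate_corr >= 1) {
      stop("mate_corr must lie in [0, 1)")
    }
    if (any(disease_prevalence <= 0) || any(disease_prevalence >= 1)) {
      stop("disease prevalences must lie in (0, 1)")
    }
    if (gwas_se < 0) stop("gwas_se must be >= 0")
  })
  invisible(cfg)
}

## variant metadata: block layout over 22 autosomes, blocks 1 Mb apart so the
## clumping window (250 kb) never spans two blocks; adjacent in-block
## variants 5 kb apart.
make_variant_table <- function(cfg) {
  m <- cfg$n_variants
  block <- rep(seq_len(ceiling(m / cfg$block_size)),
               each = cfg$block_size)[seq_len(m)]
  chrom <- ((block - 1L) %% 22L) + 1L
  ord_in_chrom <- (block - 1L) %/% 22L
  j_in_block <- stats::ave(seq_len(m), block, FUN = seq_along)
  pos <- ord_in_chrom * 1000000L + j_in_block * 5000L
  n_amb <- round(cfg$fraction_ambiguous * m)
  amb_idx <- if (n_amb > 0) sample.int(m, n_amb) else integer(0)
  amb_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                      ncol = 2, byrow = TRUE)
  ok_pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G",
                       "C", "A", "G", "A", "C", "T", "G", "T"),
                     ncol = 2, byrow = TRUE)
  pair_idx <- sample.int(nrow(ok_pairs), m, replace = TRUE)
  a1 <- ok_pairs[pair_idx, 1]
  a2 <- ok_pairs[pair_idx, 2]
  if (length(amb_idx)) {
    api <- sample.int(nrow(amb_pairs), length(amb_idx), replace = TRUE)
    a1[amb_idx] <- amb_pairs[api, 1]
    a2[amb_idx] <- amb_pairs[api, 2]
  }
  freq <- stats::runif(m, cfg$allele_freq_range[1], cfg$allele_freq_range[2])
  data.frame(id = sprintf("rs%06d", seq_len(m)),
             chrom = as.character(chrom), pos = pos,
             counted_allele = a1, other_allele = a2,
             block = block, freq = freq,
             true_weight = stats::rnorm(m, 0, cfg$weight_sd),
             stringsAsFactors = FALSE)
}

## one haplotype matrix (n x m, 0/1) from a thresholded AR(1) latent process;
## the latent correlation resets at block boundaries.
sim_haplotypes <- function(n, freq, rho, block) {
  m <- length(freq)
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) {
      if (block[j] == block[j - 1L]) {
        z[, j] <- rho * z[, j - 1L] + s * z[, j]
      }
    }
  }
  thr <- stats::qnorm(freq)
  h <- matrix(0L, n, m)
  for (j in seq_len(m)) h[, j] <- as.integer(z[, j] < thr[j])
  h
}

#' Simulate founder couples
#'
#' Draws two parents per family with block-LD haplotypes, optional two-way
#' population structure (allele-frequency divergence) and optional
#' assortative mating by deterministic rank-matching of a liability proxy
#' (the parents' standardized true polygenic score).
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_set()] of all parents in family
#'   order, haplotypes retained), `pedigree` (parent rows, founder parents
#'   coded "0"), `variants` (metadata with true weights and per-variant
#'   empirical frequencies) and `subpop` (named family-level labels).
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, "founders", {
    variants <- make_variant_table(config)
    nf <- config$n_families
    ## split families across subpops as evenly as possible
    fam_subpop <- rep(seq_len(config$n_subpops), length.out = nf)
    fam_subpop <- sort(fam_subpop)
    n_per <- tabulate(fam_subpop, nbins = config$n_subpops)

    ## direction of the between-subpop divergence per variant: by default the
    ## counted allele is uniformly more frequent in subpop 2; an aligned
    ## fraction follows the risk direction instead
    div_dir <- rep(1, nrow(variants))
    fa <- config$freq_divergence_aligned %||% 0
    if (config$n_subpops == 2 && fa > 0) {
      idx <- sample.int(nrow(variants), round(fa * nrow(variants)))
      s <- sign(variants$true_weight[idx])
      div_dir[idx] <- ifelse(s == 0, 1, s)
    }
    sexes <- integer(0)
    sub_of_person <- integer(0)
    H1 <- NULL; H2 <- NULL
    for (sp in seq_len(config$n_subpops)) {
      fq <- variants$freq
      if (config$n_subpops == 2) {
        sgn <- if (sp == 1) -1 else 1
        fq <- pmin(pmax(fq + sgn * div_dir * config$freq_divergence / 2,
                        0.01), 0.99)
      }
      n_people <- 2L * n_per[sp]
      h1 <- sim_haplotypes(n_people, fq, config$within_block_rho,
                           variants$block)
      h2 <- sim_haplotypes(n_people, fq, config$within_block_rho,
                           variants$block)
      H1 <- rbind(H1, h1); H2 <- rbind(H2, h2)
      sexes <- c(sexes, rep(c(1L, 2L), each = n_per[sp]))
      sub_of_person <- c(sub_of_person, rep(sp, n_people))
    }
    dosage <- H1 + H2

    ## liability proxy for mating: standardized true score among founders
    raw <- as.vector(dosage %*% variants$true_weight)
    L <- as.vector(scale(raw))

    ## pair males and females within subpop; rank-matching achieves spousal
    ## correlation ~ mate_corr deterministically given the seed
    father_idx <- integer(nf); mother_idx <- integer(nf)
    fam_ptr <- 0L
    offset <- 0L
    for (sp in seq_len(config$n_subpops)) {
      nmal <- n_per[sp]
      males <- offset + seq_len(nmal)
      females <- offset + nmal + seq_len(nmal)
      mc <- config$mate_corr
      if (mc > 0) {
        lm_ <- scale(L[males]); lf_ <- L[females]
        target <- mc * as.vector(lm_) +
          sqrt(1 - mc^2) * stats::rnorm(nmal)
        ## female with liability rank r goes to the male whose target has rank r
        f_ord <- order(target)
        partner <- integer(nmal)
        partner[f_ord] <- females[order(lf_)]
      } else {
        partner <- females[sample.int(nmal)]
      }
      father_idx[fam_ptr + seq_len(nmal)] <- males
      mother_idx[fam_ptr + seq_len(nmal)] <- partner
      fam_ptr <- fam_ptr + nmal
      offset <- offset + 2L * nmal
    }

    ## reorder founders into family order: father_1, mother_1, father_2, ...
    ord <- as.vector(rbind(father_idx, mother_idx))
    fam_ids <- sprintf("FAM%05d", seq_len(nf))
    ids <- as.vector(rbind(paste0(fam_ids, "_F"), paste0(fam_ids, "_M")))
    geno <- genotype_set(dosage[ord, , drop = FALSE],
                         variants[, c("id", "chrom", "pos",
                                      "counted_allele", "other_allele")],
                         ids,
                         haplotypes = list(H1[ord, , drop = FALSE],
                                           H2[ord, , drop = FALSE]))
    variants$freq_emp <- colMeans(dosage) / 2
    ped <- data.frame(family_id = rep(fam_ids, each = 2),
                      individual_id = ids,
                      father_id = "0", mother_id = "0",
                      sex = rep(c(1L, 2L), nf),
                      stringsAsFactors = FALSE)
    subpop <- stats::setNames(fam_subpop, fam_ids)
    list(genotypes = geno, pedigree = ped, variants = variants,
         subpop = subpop)
  })
}

#' Build the offspring rows of a pedigree
#'
#' @param parent_pedigree parent rows as returned by [simulate_founders()].
#' @param config a [sim_config()].
#' @return data.frame of offspring pedigree rows (FID, IID, PAT, MAT, SEX).
#' @export
offspring_pedigree <- function(parent_pedigree, config) {
  fams <- unique(parent_pedigree$family_id)
  k <- config$sibs_per_family
  with_substream(config$seed, "pedigree", {
    data.frame(
      family_id = rep(fams, each = k),
      individual_id = paste0(rep(fams, each = k), "_S",
                             rep(seq_len(k), length(fams))),
      father_id = rep(paste0(fams, "_F"), each = k),
      mother_id = rep(paste0(fams, "_M"), each = k),
      sex = sample(c(1L, 2L), k * length(fams), replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Mendelian transmission from parents to offspring
#'
#' Each offspring receives one of the two parental haplotypes per LD block
#' from each parent, chosen uniformly and independently across blocks and
#' offspring (no recombination within blocks). Dosage is the allele sum.
#'
#' @param parents founder [genotype_set()] with haplotypes.
#' @param pedigree pedigree containing offspring rows (non-"0" parent ids).
#' @param config a [sim_config()].
#' @return a [genotype_set()] for the offspring, haplotypes retained.
#' @export
transmit <- function(parents, pedigree, config) {
  if (is.null(parents$haplotypes)) {
    stop("parents must carry haplotypes for transmission")
  }
  off <- pedigree[pedigree$father_id != "0" | pedigree$mother_id != "0", ,
                  drop = FALSE]
  if (nrow(off) == 0) stop("pedigree has no offspring rows")
  bad <- off$father_id == "0" | off$mother_id == "0"
  if (any(bad)) {
    stop("missing parent for family ", off$family_id[bad][1])
  }
  fi <- match(off$father_id, parents$sample_ids)
  mi <- match(off$mother_id, parents$sample_ids)
  if (anyNA(fi) || anyNA(mi)) {
    miss <- off$family_id[is.na(fi) | is.na(mi)][1]
    stop("parent genotypes not found for family ", miss)
  }
  v <- parents$variants
  ## block structure recovered from positions: new block at chromosome change
  ## or gap > 250 kb (blocks were laid out 1 Mb apart)
  newb <- c(TRUE, v$chrom[-1] != v$chrom[-nrow(v)] |
              diff(v$pos) > 250000 | diff(v$pos) < 0)
  block <- cumsum(newb)
  nb <- max(block)
  n <- nrow(off)
  H1p <- parents$haplotypes[[1]]; H2p <- parents$haplotypes[[2]]
  with_substream(config$seed, "transmit", {
    gam <- function(pidx) {
      choice <- matrix(stats::runif(n * nb) < 0.5, n, nb)[, block, drop = FALSE]
      h1 <- H1p[pidx, , drop = FALSE]
      h2 <- H2p[pidx, , drop = FALSE]
      ifelse(choice, h1, h2)
    }
    gf <- gam(fi)
    gm <- gam(mi)
    genotype_set(gf + gm, v, off$individual_id,
                 haplotypes = list(matrix(as.integer(gf), nrow(gf)),
                                   matrix(as.integer(gm), nrow(gm))))
  })
}

#' Assemble the ground-truth ledger
#'
#' Records, for parameter-recovery tests, the per-variant true weights, each
#' offspring's true standardized PGS (dosage-weight sum standardized over the
#' offspring cohort), the midparent PGS (average of the two parents' scores,
#' each standardized over the founder cohort so that under random mating the
#' midparent has variance 1/2 on the child scale), and family labels.
#'
#' @param founders output of [simulate_founders()].
#' @param offspring offspring [genotype_set()].
#' @param pedigree full pedigree (parent + offspring rows).
#' @return list of class `truth_ledger`.
#' @export
build_truth <- function(founders, offspring, pedigree) {
  w <- founders$variants$true_weight
  raw_off <- as.vector(offspring$dosage %*% w)
  pgs_true <- stats::setNames(as.vector(scale(raw_off)),
                              offspring$sample_ids)
  raw_par <- as.vector(founders$genotypes$dosage %*% w)
  par_std <- stats::setNames(as.vector(scale(raw_par)),
                             founders$genotypes$sample_ids)
  off_rows <- pedigree[match(offspring$sample_ids, pedigree$individual_id), ]
  midparent <- (par_std[off_rows$father_id] + par_std[off_rows$mother_id]) / 2
  names(midparent) <- offspring$sample_ids
  structure(list(variants = founders$variants,
                 pgs_true = pgs_true,
                 midparent_pgs = midparent,
                 parent_pgs = par_std,
                 family_id = stats::setNames(off_rows$family_id,
                                             offspring$sample_ids),
                 subpop = founders$subpop),
            class = "truth_ledger")
}

#' Simulate GWAS summary statistics around the true weights
#'
#' Estimated log-odds = true weight + Normal(0, gwas_se^2); Wald p-values;
#' reported MAF/INFO mostly clean, with configured fractions pushed below the
#' MAF and INFO QC cutoffs, and a configured fraction of rows reported on the
#' opposite allele (weight negated) to exercise harmonization.
#'
#' @param truth a `truth_ledger` (or the list from [simulate_founders()]);
#'   must carry `$variants` with true weights.
#' @param config a [sim_config()].
#' @return data.frame of class `summary_stats` with columns id, chrom, pos,
#'   effect_allele, other_allele, weight, se, p, maf, info.
#' @export
simulate_sumstats <- function(truth, config) {
  if (config$gwas_se < 0) stop("gwas_se must be >= 0")
  v <- truth$variants
  m <- nrow(v)
  with_substream(config$seed, "sumstats", {
    beta <- v$true_weight + if (config$gwas_se > 0) {
      stats::rnorm(m, 0, config$gwas_se)
    } else 0
    se <- rep(config$gwas_se, m)
    if (config$gwas_se > 0) {
      z <- beta / se
      p <- 2 * stats::pnorm(-abs(z))
      p <- pmin(pmax(p, 1e-300), 1)
    } else {
      p <- ifelse(beta == 0, 1, 1e-300)
    }
    frq <- v$freq_emp %||% v$freq
    maf <- pmin(frq, 1 - frq)
    maf <- pmax(maf, 1e-4)
    info <- stats::runif(m, 0.9, 1)
    n_maf <- round(config$fraction_low_maf * m)
    if (n_maf > 0) {
      i <- sample.int(m, n_maf)
      maf[i] <- stats::runif(n_maf, 0.001, 0.009)
    }
    n_info <- round(config$fraction_low_info * m)
    if (n_info > 0) {
      i <- sample.int(m, n_info)
      info[i] <- stats::runif(n_info, 0.4, 0.79)
    }
    a1 <- v$counted_allele
    a2 <- v$other_allele
    n_fl <- round(config$fraction_flipped * m)
    if (n_fl > 0) {
      i <- sample.int(m, n_fl)
      tmp <- a1[i]; a1[i] <- a2[i]; a2[i] <- tmp
      beta[i] <- -beta[i]
    }
    ss <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                     effect_allele = a1, other_allele = a2,
                     weight = beta, se = se, p = p, maf = maf, info = info,
                     stringsAsFactors = FALSE)
    class(ss) <- c("summary_stats", "data.frame")
    ss
  })
}

#' Simulate phenotypes, covariates and medication flags
#'
#' The continuous outcome follows
#' `Y = beta_direct * S_child + beta_nurture * midparent + F + e` with a
#' family-level environment `F ~ N(subpop shift, var_shared_env)` and
#' residual `e ~ N(0, var_noise)`. Each binary disease is generated by
#' thresholding a fresh liability of the same form at its (1 - prevalence)
#' empirical quantile. Raw-scale biomarkers (LDL, triglycerides, blood
#' pressure, glucose, HbA1c, BMI) are monotone rescalings of further fresh
#' liabilities; medication flags mark samples above `med_flag_quantile` of
#' the corresponding biomarker. Age, sex, education, chip and genotype-PC
#' covariates are attached.
#'
#' @param genotypes offspring [genotype_set()].
#' @param pedigree full pedigree.
#' @param truth `truth_ledger` from [build_truth()].
#' @param config a [sim_config()].
#' @return data.frame (the phenotype table), one row per offspring.
#' @export
simulate_phenotypes <- function(genotypes, pedigree, truth, config) {
  ids <- genotypes$sample_ids
  n <- length(ids)
  S <- truth$pgs_true[ids]
  Sb <- truth$midparent_pgs[ids]
  fam <- truth$family_id[ids]
  fams <- unique(fam)
  with_substream(config$seed, "phenotypes", {
    Ff <- stats::rnorm(length(fams), 0, sqrt(config$var_shared_env))
    if (config$n_subpops == 2 && config$subpop_env_shift != 0) {
      Ff <- Ff + config$subpop_env_shift *
        (truth$subpop[fams] == 2)
    }
    Ffam <- stats::setNames(Ff, fams)[fam]
    liability <- function() {
      config$beta_direct * S + config$beta_nurture * Sb + Ffam +
        stats::rnorm(n, 0, sqrt(config$var_noise))
    }
    y <- liability()

    pheno <- data.frame(family_id = fam, individual_id = ids,
                        stringsAsFactors = FALSE)
    prow <- pedigree[match(ids, pedigree$individual_id), ]
    pheno$sex <- prow$sex
    pheno$age <- pmin(pmax(stats::rnorm(n, 44.4, 13.6), 18), 90)
    cats <- education_categories()
    pheno$education_category <- sample(
      cats, n, replace = TRUE,
      prob = c(0.01, 0.06, 0.15, 0.12, 0.22, 0.175, 0.165, 0.10))
    chip_fam <- stats::setNames(
      sample(c("GSA", "Cyto"), length(fams), replace = TRUE,
             prob = c(0.715, 0.285)), fams)
    pheno$chip <- chip_fam[fam]

    pheno$biomarker <- y
    for (d in names(config$disease_prevalence)) {
      prev <- config$disease_prevalence[[d]]
      if (prev * n < 20) {
        warning("expected case count below 20 for ", d, call. = FALSE)
      }
      ld <- liability()
      pheno[[d]] <- as.integer(ld > stats::quantile(ld, 1 - prev))
    }

    lz <- function() as.vector(scale(liability()))
    pheno$ldl <- 3.25 + 0.93 * lz()
    pheno$triglycerides <- exp(-0.05 + 0.45 * lz())
    pheno$sbp <- 126.6 + 16.6 * lz()
    pheno$dbp <- 74.3 + 10.1 * lz()
    pheno$glucose <- 4.96 + 0.73 * lz()
    pheno$hba1c <- 5.49 + 0.32 * lz()
    pheno$bmi <- pmax(26 + 4 * lz(), 14)

    qflag <- function(x) {
      as.integer(x > stats::quantile(x, config$med_flag_quantile))
    }
    pheno$chol_med <- qflag(pheno$ldl)
    pheno$bp_med <- qflag(pheno$sbp)
    pheno$diabetic_med <- qflag(pheno$glucose)

    adhd_liab <- S + stats::rnorm(n)
    pheno$adhd <- as.integer(adhd_liab > stats::quantile(adhd_liab, 1 - 0.0082))

    k <- min(8L, n - 1L, nrow(genotypes$variants))
    pcs <- compute_genotype_pcs(genotypes, k = k)
    for (j in seq_len(ncol(pcs))) pheno[[paste0("PC", j)]] <- pcs[, j]
    pheno
  })
}

education_categories <- function() {
  c("no education (did not finish primary school)",
    "primary education",
    "lower or preparatory secondary vocational education",
    "junior general secondary education",
    "secondary vocational education",
    "senior general secondary education",
    "higher vocational education",
    "university education")
}

#' Run the whole generator
#'
#' Founders -> offspring pedigree -> Mendelian transmission -> truth ledger
#' -> summary statistics -> phenotypes, all from one master seed.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `founders`, `genotypes` (offspring),
#'   `pedigree` (parents + offspring), `truth`, `sumstats`, `phenotypes`.
#' @export
simulate_cohort <- function(config) {
  founders <- simulate_founders(config)
  off_ped <- offspring_pedigree(founders$pedigree, config)
  ped <- rbind(founders$pedigree, off_ped)
  genotypes <- transmit(founders$genotypes, ped, config)
  truth <- build_truth(founders, genotypes, ped)
  sumstats <- simulate_sumstats(truth, config)
  phenotypes <- simulate_phenotypes(genotypes, ped, truth, config)
  list(config = config, founders = founders, genotypes = genotypes,
       pedigree = ped, truth = truth, sumstats = sumstats,
       phenotypes = phenotypes)
}
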