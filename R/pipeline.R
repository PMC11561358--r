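#' Read a pipeline run configuration
#'
#' YAML configuration with keys: `seed`, `stages` (subset of simulate, pgs,
#' prep, assoc, sibling), `out_dir`, `sim` (overrides for [sim_config()]),
#' `pgs` (`r2_max`, `window_kb`, `thresholds`), `paths` (input files for
#' non-simulated runs: `sumstats`, `genotypes`, `reference`, `pedigree`,
#' `phenotypes`), `models` (list of `outcome`/`link` pairs), `covariates`,
#' `sensitivity` (`exclude_adhd`, `adjust_bmi`), and `fdr`
#' (`combined`/`per_family`).
#'
#' @param path YAML file.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a plain list with the same structure.
#' @export
as_run_config <- function(cfg) {
  cfg$seed <- cfg$seed %||% 1L
  cfg$stages <- cfg$stages %||% c("simulate", "pgs", "prep", "assoc",
                                  "sibling")
  bad <- setdiff(cfg$stages, c("simulate", "pgs", "prep", "assoc",
                               "sibling"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$pgs <- cfg$pgs %||% list()
  cfg$sensitivity <- cfg$sensitivity %||% list()
  cfg$fdr <- cfg$fdr %||% "combined"
  if (is.null(cfg$models)) {
    cfg$models <- list(list(outcome = "metabolic_disease", link = "logit"),
                       list(outcome = "cardiovascular_disease",
                            link = "logit"),
                       list(outcome = "biomarker", link = "identity"))
  }
  class(cfg) <- "run_config"
  cfg
}

default_covariate_terms <- function(data, n_pcs = 8) {
  pcs <- paste0("PC", seq_len(n_pcs))
  pcs <- pcs[pcs %in% names(data)]
  c("age", "sex", "chip", pcs, paste0("chip:", pcs))
}

stage_step <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the simulate -> pgs -> prep -> assoc -> sibling pipeline
#'
#' Executes the requested stages from one configuration and master seed,
#' writes result and report TSVs plus a run manifest into `out_dir`, and
#' applies one combined Benjamini-Hochberg adjustment across all
#' association tests of the run (the FDR family), or one per results table
#' when `fdr: per_family`.
#'
#' @param config a `run_config` (from [read_run_config()] /
#'   [as_run_config()]) or a path to a YAML file.
#' @param out_dir output directory (created; defaults to
#'   `config$out_dir`).
#' @return (invisibly) the output directory; side effect: result files.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  cohort <- NULL
  sumstats <- genotypes <- reference <- pedigree <- pheno <- NULL
  if ("simulate" %in% config$stages) {
    stage_step("simulate", {
      sim_args <- config$sim %||% list()
      sim_args$seed <- config$seed
      scfg <- do.call(sim_config, sim_args)
      cohort <- simulate_cohort(scfg)
      sumstats <- cohort$sumstats
      genotypes <- cohort$genotypes
      reference <- cohort$founders$genotypes
      pedigree <- cohort$pedigree
      pheno <- cohort$phenotypes
      write_sumstats(sumstats, file.path(out_dir, "sumstats.tsv"))
      write_pedigree(pedigree, file.path(out_dir, "pedigree.ped"))
      write_phenotypes(pheno, file.path(out_dir, "phenotypes.tsv"))
      write_truth(cohort$truth, file.path(out_dir, "truth.tsv"))
      if (isTRUE(config$write_genotypes)) {
        write_genotypes_tsv(genotypes, file.path(out_dir, "genotypes.tsv"))
      }
      counts$simulate <- c(samples = length(genotypes$sample_ids),
                           variants = nrow(genotypes$variants))
    })
  } else {
    stage_step("load", {
      p <- config$paths %||% list()
      if (!is.null(p$sumstats)) sumstats <- read_sumstats(p$sumstats)
      if (!is.null(p$genotypes)) {
        genotypes <- if (grepl("\\.vcf(\\.gz)?$", p$genotypes)) {
          read_genotypes_vcf(p$genotypes)
        } else read_genotypes_tsv(p$genotypes)
      }
      reference <- if (!is.null(p$reference)) {
        if (grepl("\\.vcf(\\.gz)?$", p$reference)) {
          read_genotypes_vcf(p$reference)
        } else read_genotypes_tsv(p$reference)
      } else genotypes
      if (!is.null(p$pedigree)) pedigree <- read_pedigree(p$pedigree)
      if (!is.null(p$phenotypes)) pheno <- read_phenotypes(p$phenotypes)
    })
  }

  pgs <- NULL
  if ("pgs" %in% config$stages) {
    stage_step("pgs", {
      if (is.null(sumstats) || is.null(genotypes)) {
        stop("needs sumstats and genotypes")
      }
      pp <- pgs_pipeline(sumstats, genotypes,
                         reference = reference %||% genotypes,
                         r2_max = config$pgs$r2_max %||% 0.1,
                         window_bp = 1000 *
                           (config$pgs$window_kb %||% 250),
                         thresholds = config$pgs$thresholds %||%
                           pgs_thresholds())
      pgs <- pp$pgs
      utils::write.table(
        data.frame(IID = names(pgs), score = num17(unname(pgs))),
        file.path(out_dir, "pgs.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(pp$qc, file.path(out_dir, "pgs_qc_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts$pgs <- c(scored = length(pgs),
                      clumped = length(pp$clumped))
    })
  }

  if ("prep" %in% config$stages) {
    stage_step("prep", {
      if (is.null(pheno)) stop("needs phenotypes")
      pr <- prep_phenotypes(pheno)
      pheno <- pr$pheno
      if ("bmi" %in% names(pheno)) {
        pheno$obesity <- derive_obesity(pheno$bmi)
      }
      if ("education_category" %in% names(pheno)) {
        em <- map_education(pheno$education_category)
        pheno$education_years <- em$years
        pheno$education_level <- em$level
      }
      write_phenotypes(pheno, file.path(out_dir, "phenotypes_clean.tsv"))
      utils::write.table(pr$report, file.path(out_dir, "prep_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts$prep <- c(rows = nrow(pheno))
    })
  }

  results <- NULL
  if ("assoc" %in% config$stages) {
    stage_step("assoc", {
      if (is.null(pgs) || is.null(pheno)) stop("needs pgs and phenotypes")
      pheno$PGS <- unname(pgs[pheno$individual_id])
      covs <- config$covariates %||% default_covariate_terms(pheno)
      rows <- list()
      for (mdl in config$models) {
        spec <- model_spec(mdl$outcome, link = mdl$link,
                           covariates = covs)
        rows[[length(rows) + 1]] <-
          run_association(spec, pheno, model_label = "main")
        if (isTRUE(config$sensitivity$exclude_adhd)) {
          spec2 <- spec; spec2$filter <- function(d) d$adhd == 0
          rows[[length(rows) + 1]] <-
            run_association(spec2, pheno,
                            model_label = "sensitivity:exclude_adhd")
        }
        if (isTRUE(config$sensitivity$adjust_bmi)) {
          spec3 <- model_spec(mdl$outcome, link = mdl$link,
                              covariates = c(covs, "bmi"))
          rows[[length(rows) + 1]] <-
            run_association(spec3, pheno,
                            model_label = "sensitivity:adjust_bmi")
        }
      }
      results <- do.call(rbind, lapply(rows, function(r) {
        r[, results_columns()[results_columns() %in% names(r)]]
      }))
      counts$assoc <- c(tests = nrow(results))
    })
  }

  sib_results <- NULL
  if ("sibling" %in% config$stages) {
    stage_step("sibling", {
      if (is.null(pedigree)) stop("needs a pedigree")
      if (is.null(pgs) || is.null(pheno)) stop("needs pgs and phenotypes")
      if (!"PGS" %in% names(pheno)) {
        pheno$PGS <- unname(pgs[pheno$individual_id])
      }
      covs <- config$covariates %||% default_covariate_terms(pheno)
      rows <- lapply(config$models, function(mdl) {
        spec <- model_spec(mdl$outcome, link = mdl$link,
                           covariates = covs)
        run_sibling(pheno, pedigree, spec)
      })
      sib_results <- do.call(rbind, rows)
      counts$sibling <- c(outcomes = nrow(sib_results))
    })
  }

  ## one combined FDR family across every test of the run
  if (!is.null(results)) {
    fam_p <- results$p
    if (identical(config$fdr, "combined") && !is.null(sib_results)) {
      all_p <- c(results$p, sib_results$p_compare)
      adj <- bh_fdr(all_p)
      results$p_fdr <- adj[seq_len(nrow(results))]
      sib_results$p_compare_fdr <- adj[-seq_len(nrow(results))]
    } else {
      results$p_fdr <- bh_fdr(fam_p)
      if (!is.null(sib_results)) {
        sib_results$p_compare_fdr <- bh_fdr(sib_results$p_compare)
      }
    }
    write_results(results, file.path(out_dir, "results.tsv"))
  }
  if (!is.null(sib_results)) {
    out <- sib_results
    for (cc in setdiff(names(out), "outcome")) {
      out[[cc]] <- ifelse(is.na(out[[cc]]), "NA",
                          sprintf("%.17g", out[[cc]]))
    }
    utils::write.table(out, file.path(out_dir, "sib_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- c(
    paste0("package_version\t",
           as.character(utils::packageVersion("sibscore"))),
    paste0("seed\t", config$seed),
    paste0("stages\t", paste(config$stages, collapse = ",")),
    paste0("fdr_family\t", config$fdr),
    paste0("n_tests\t", if (is.null(results)) 0 else nrow(results)),
    vapply(names(counts), function(s) {
      paste0("rows_", s, "\t",
             paste(names(counts[[s]]), counts[[s]], sep = "=",
                   collapse = ","))
    }, character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
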