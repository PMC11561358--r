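#' Identify full-sibling groups
#'
#' Groups individuals sharing the same non-missing father and mother and
#' keeps groups with at least two members among the analysable samples.
#' Half-siblings (one shared parent) never form a stratum.
#'
#' @param pedigree pedigree data.frame (family_id, individual_id, father_id,
#'   mother_id, sex; missing parent "0").
#' @param samples character vector of individuals with usable genotype and
#'   phenotype data.
#' @return data.frame (individual_id, family_id, sibship_id) covering the
#'   retained siblings, with attribute `counts` (individuals, sibships,
#'   singletons).
#' @export
build_sibships <- function(pedigree, samples) {
  p <- pedigree[pedigree$individual_id %in% samples, , drop = FALSE]
  p <- p[p$father_id != "0" & p$mother_id != "0", , drop = FALSE]
  if (nrow(p) == 0) {
    warning("no individuals with two known parents", call. = FALSE)
    out <- data.frame(individual_id = character(0),
                      family_id = character(0),
                      sibship_id = character(0))
    attr(out, "counts") <- c(individuals = 0L, sibships = 0L,
                             singletons = 0L)
    return(out)
  }
  key <- paste(p$father_id, p$mother_id, sep = "|")
  size <- table(key)
  keep <- key %in% names(size)[size >= 2]
  if (!any(keep)) warning("no sibships of size >= 2", call. = FALSE)
  out <- data.frame(individual_id = p$individual_id[keep],
                    family_id = p$family_id[keep],
                    sibship_id = key[keep],
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(individuals = sum(keep),
                           sibships = length(unique(key[keep])),
                           singletons = sum(!keep))
  out
}

#' Decompose a polygenic score into sibship mean and deviation
#'
#' Within-sibship deviations are the component of the PGS created by random
#' segregation at meiosis; the sibship mean carries everything shared by the
#' family (parental genotypes, stratification, assortment).
#'
#' @param sibships data.frame from [build_sibships()].
#' @param pgs named numeric vector of scores (names = individual ids).
#' @return data.frame with columns individual_id, sibship_id, pgs,
#'   pgs_mean, pgs_dev; deviations sum to zero exactly within every
#'   sibship.
#' @export
decompose_pgs <- function(sibships, pgs) {
  x <- pgs[sibships$individual_id]
  if (anyNA(x)) stop("PGS missing for ",
                     sum(is.na(x)), " sibship member(s)")
  m <- stats::ave(x, sibships$sibship_id)
  data.frame(individual_id = sibships$individual_id,
             sibship_id = sibships$sibship_id,
             pgs = unname(x), pgs_mean = unname(m),
             pgs_dev = unname(x - m), stringsAsFactors = FALSE)
}

## demean columns of a matrix within strata
demean_within <- function(M, strata) {
  apply(M, 2, function(col) col - stats::ave(col, strata))
}

#' Within-sibling fixed-effects regression (continuous outcome)
#'
#' Outcome and regressors are demeaned within sibship (absorbing the family
#' fixed effects) and fitted by least squares; the standard error is a
#' sibship-clustered sandwich with a degrees-of-freedom correction for the
#' absorbed means. Covariates that are constant within every sibship are
#' absorbed by the fixed effects and dropped.
#'
#' @param data data.frame with the analysis rows (sibship members only).
#' @param outcome,exposure column names.
#' @param covariates character vector of covariate columns.
#' @param sibship sibship id column (default "sibship_id").
#' @return list with `estimate`, `se`, `coef`, `vcov`, `n`, `n_sibships`,
#'   `dropped` (absorbed covariates).
#' @export
fit_within_linear <- function(data, outcome, exposure,
                              covariates = character(0),
                              sibship = "sibship_id") {
  sid <- data[[sibship]]
  sz <- table(sid)
  if (all(sz < 2)) stop("all sibships have fewer than 2 members")
  y <- data[[outcome]]
  f <- stats::reformulate(c(exposure, covariates))
  X <- stats::model.matrix(f, data)[, -1, drop = FALSE]
  yd <- y - stats::ave(y, sid)
  Xd <- demean_within(X, sid)
  absorbed <- apply(Xd, 2, function(c) max(abs(c)) < 1e-10)
  dropped <- colnames(Xd)[absorbed]
  if (all(absorbed)) stop("all regressors are family-constant")
  Xd <- Xd[, !absorbed, drop = FALSE]
  fit <- fit_glm(yd, Xd, "identity")
  G <- length(unique(sid))
  N <- fit$n
  p <- ncol(fit$X)
  sw <- sandwich_se(fit, sid)
  dof <- (N - 1) / max(N - G - p, 1)
  V <- sw$vcov * dof
  se <- sqrt(diag(V))
  exl <- match(exposure, colnames(fit$X))
  list(estimate = unname(fit$coef[exl]), se = unname(se[exl]),
       coef = fit$coef, vcov = V, n = N, n_sibships = G,
       dropped = dropped, fit = fit)
}

## conditional-logistic log-likelihood, gradient and Hessian for one
## stratum via the recursive denominator polynomial B(j, r)
clogit_stratum <- function(eta, X, case) {
  k <- sum(case)
  m <- length(eta)
  c0 <- mean(eta)
  w <- exp(eta - c0)
  p <- ncol(X)
  B <- numeric(k + 1); B[1] <- 1
  dB <- matrix(0, k + 1, p)
  d2B <- array(0, c(k + 1, p, p))
  for (j in seq_len(m)) {
    xj <- X[j, ]
    xx <- tcrossprod(xj)
    for (r in rev(seq_len(min(j, k)))) {
      d2B[r + 1, , ] <- d2B[r + 1, , ] +
        w[j] * (xx * B[r] + outer(xj, dB[r, ]) + outer(dB[r, ], xj) +
                  d2B[r, , ])
      dB[r + 1, ] <- dB[r + 1, ] + w[j] * (xj * B[r] + dB[r, ])
      B[r + 1] <- B[r + 1] + w[j] * B[r]
    }
  }
  Bk <- B[k + 1]
  g <- dB[k + 1, ] / Bk
  H <- d2B[k + 1, , ] / Bk - tcrossprod(g)
  list(ll = sum(eta[case]) - k * c0 - log(Bk),
       grad = colSums(X[case, , drop = FALSE]) - g,
       hess = -H)
}

#' Within-sibling conditional logistic regression (binary outcome)
#'
#' Maximizes the conditional likelihood that, within each sibship, the
#' observed members are the cases given the number of cases in the stratum
#' (the family intercepts cancel). Outcome-concordant sibships contribute no
#' information and are counted. Newton-Raphson is run to gradient norm
#' < 1e-8; the denominator uses the recursive polynomial algorithm, so large
#' sibships need no exhaustive enumeration.
#'
#' @param data analysis rows (sibship members only).
#' @param outcome,exposure column names (outcome 0/1).
#' @param covariates covariate columns; family-constant columns are dropped
#'   (they are absorbed by the stratification).
#' @param sibship sibship id column.
#' @return list with `estimate`, `se` (observed information), `coef`,
#'   `vcov`, `ll`, `n`, `n_sibships`, `n_discordant`, `non_estimable`.
#' @export
fit_within_logistic <- function(data, outcome, exposure,
                                covariates = character(0),
                                sibship = "sibship_id") {
  sid <- as.character(data[[sibship]])
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")
  f <- stats::reformulate(c(exposure, covariates))
  X <- stats::model.matrix(f, data)[, -1, drop = FALSE]
  Xd <- demean_within(X, sid)
  absorbed <- apply(Xd, 2, function(c) max(abs(c)) < 1e-10)
  if (any(absorbed)) {
    message("dropping family-constant covariate(s): ",
            paste(colnames(X)[absorbed], collapse = ", "))
    X <- X[, !absorbed, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no stratum-varying regressors left")
  strata <- split(seq_along(y), sid)
  ncase <- vapply(strata, function(i) sum(y[i]), numeric(1))
  nmem <- lengths(strata)
  informative <- ncase > 0 & ncase < nmem
  n_disc <- sum(informative)
  if (n_disc == 0) {
    return(list(estimate = NA_real_, se = NA_real_, coef = NULL,
                vcov = NULL, ll = NA_real_, n = length(y),
                n_sibships = length(strata), n_discordant = 0L,
                non_estimable = TRUE))
  }
  strata <- strata[informative]
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(100)) {
    ll <- 0; g <- rep(0, p); H <- matrix(0, p, p)
    for (i in strata) {
      s <- clogit_stratum(as.vector(X[i, , drop = FALSE] %*% beta),
                          X[i, , drop = FALSE], y[i] == 1)
      ll <- ll + s$ll; g <- g + s$grad; H <- H + s$hess
    }
    if (max(abs(g)) < 1e-8) { converged <- TRUE; break }
    step <- solve(-H, g)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
  }
  V <- solve(-H)
  dimnames(V) <- list(colnames(X), colnames(X))
  exl <- match(colnames(X)[1], colnames(X))
  est <- stats::setNames(beta, colnames(X))
  list(estimate = unname(est[1]), se = sqrt(V[1, 1]), coef = est,
       vcov = V, ll = ll, n = length(y), n_sibships = length(ncase),
       n_discordant = n_disc,
       non_estimable = !converged || any(abs(beta) > 15))
}

#' Conditional-logistic log-likelihood at given coefficients
#'
#' Exposes the stratified likelihood itself (used for oracle checks against
#' exhaustive enumeration over case assignments).
#'
#' @param beta coefficient vector.
#' @param X design matrix (no intercept).
#' @param y 0/1 outcome.
#' @param strata stratum ids.
#' @return log-likelihood over the outcome-discordant strata.
#' @export
clogit_loglik <- function(beta, X, y, strata) {
  X <- as.matrix(X)
  idx <- split(seq_along(y), strata)
  ll <- 0
  for (i in idx) {
    k <- sum(y[i])
    if (k == 0 || k == length(i)) next
    s <- clogit_stratum(as.vector(X[i, , drop = FALSE] %*% beta),
                        X[i, , drop = FALSE], y[i] == 1)
    ll <- ll + s$ll
  }
  ll
}

#' Formal between-versus-within comparison of the PGS coefficient
#'
#' Primary method: a joint decomposition model regressing the outcome on
#' the sibship-mean PGS and the within-sibship deviation (plus covariates),
#' with sibship-clustered sandwich covariance, and a Wald test that the two
#' coefficients are equal. A secondary z statistic comparing two separately
#' fitted coefficients, `z = (b_B - b_W) / sqrt(SE_B^2 + SE_W^2)`, is
#' reported for reference.
#'
#' @param data analysis rows with columns `pgs_mean` and `pgs_dev` (from
#'   [decompose_pgs()]).
#' @param outcome outcome column.
#' @param link "identity" or "logit".
#' @param covariates covariate columns.
#' @param sibship sibship id column.
#' @param b_between,se_between,b_within,se_within optional separately fitted
#'   coefficients for the secondary z method.
#' @return list with `b_mean`, `b_dev`, their sandwich covariance, `p_wald`
#'   (primary) and `p_z` (secondary, NA when the separate fits are not
#'   supplied).
#' @export
compare_between_within <- function(data, outcome, link = "identity",
                                   covariates = character(0),
                                   sibship = "sibship_id",
                                   b_between = NULL, se_between = NULL,
                                   b_within = NULL, se_within = NULL) {
  stopifnot(all(c("pgs_mean", "pgs_dev") %in% names(data)))
  y <- data[[outcome]]
  if (link == "identity") y <- zscore(y)
  covs <- prune_constant_terms(covariates, data)
  f <- stats::reformulate(c("pgs_mean", "pgs_dev", covs))
  X <- stats::model.matrix(f, data)
  fit <- fit_glm(y, X, link)
  sw <- sandwich_se(fit, data[[sibship]])
  bm <- fit$coef["pgs_mean"]; bd <- fit$coef["pgs_dev"]
  V <- sw$vcov
  vd <- V["pgs_mean", "pgs_mean"] + V["pgs_dev", "pgs_dev"] -
    2 * V["pgs_mean", "pgs_dev"]
  db <- bm - bd
  ## numerically identical coefficients carry no evidence of a difference
  ## (guards the degenerate noise-free case where vd is also ~0)
  z <- if (abs(db) <= 1e-10 * max(1, abs(bm), abs(bd))) 0 else
    db / sqrt(vd)
  p_z <- NA_real_
  if (!is.null(b_between) && !is.null(b_within)) {
    zz <- (b_between - b_within) / sqrt(se_between^2 + se_within^2)
    p_z <- 2 * stats::pnorm(-abs(zz))
  }
  list(b_mean = unname(bm), b_dev = unname(bd), vcov = V,
       z_wald = unname(z), p_wald = unname(2 * stats::pnorm(-abs(z))),
       p_z = p_z, fit = fit)
}

#' Attenuation of the between-sibling coefficient in the within model
#'
#' `100 * (b_within - b_between) / b_between`, on the log-OR scale for
#' logistic models. Undefined (NA) when the between coefficient is zero.
#'
#' @param b_between,b_within coefficients on the same (log-OR/beta) scale.
#' @return percent change.
#' @export
attenuation_pct <- function(b_between, b_within) {
  ifelse(is.na(b_between) | b_between == 0, NA_real_,
         100 * (b_within - b_between) / b_between)
}

#' Full within-sibling analysis for one outcome
#'
#' Refits the population model on the sibling subsample (the
#' between-sibling reference), fits the within-sibling model (fixed effects
#' for continuous outcomes, conditional logistic for binary outcomes), runs
#' the formal between-within comparison on the joint decomposition model,
#' and summarizes the attenuation.
#'
#' @param data phenotype table (all samples; the sibling subsample is
#'   selected internally).
#' @param pedigree pedigree table.
#' @param spec a [model_spec()] for the outcome.
#' @return one-row data.frame: outcome, n_individuals, n_sibships,
#'   n_discordant (NA for continuous outcomes), b_between, se_between,
#'   b_within, se_within, pct_change, p_compare; `p_compare_fdr` is NA
#'   until [bh_fdr()] is applied across outcomes.
#' @export
run_sibling <- function(data, pedigree, spec) {
  if (!is.null(spec$filter)) data <- data[spec$filter(data), , drop = FALSE]
  used <- unique(c(spec$outcome, spec$exposure,
                   term_columns(spec$covariates), spec$cluster))
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  sibs <- build_sibships(pedigree, d$individual_id)
  d <- d[match(sibs$individual_id, d$individual_id), , drop = FALSE]
  d$sibship_id <- sibs$sibship_id
  ## between-sibling reference: the population model on the sibling subsample
  spec_sib <- spec
  spec_sib$filter <- NULL
  between <- run_association(spec_sib, d, model_label = "between_sibling")
  ## decomposition for the comparison test
  pgs <- stats::setNames(d[[spec$exposure]], d$individual_id)
  pgs <- stats::setNames(as.vector(scale(pgs)), names(pgs))
  dec <- decompose_pgs(sibs, pgs)
  d$pgs_mean <- dec$pgs_mean[match(d$individual_id, dec$individual_id)]
  d$pgs_dev <- dec$pgs_dev[match(d$individual_id, dec$individual_id)]
  d$.pgs_std <- unname(pgs[d$individual_id])
  covs <- prune_constant_terms(spec$covariates, d)
  if (spec$link == "identity") {
    w <- fit_within_linear(d, spec$outcome, ".pgs_std", covs)
    n_disc <- NA_integer_
  } else {
    w <- fit_within_logistic(d, spec$outcome, ".pgs_std", covs)
    n_disc <- w$n_discordant
  }
  cmp <- compare_between_within(d, spec$outcome, spec$link, covs,
                                b_between = between$estimate,
                                se_between = between$se,
                                b_within = w$estimate,
                                se_within = w$se)
  res <- data.frame(outcome = spec$outcome,
                    n_individuals = nrow(d),
                    n_sibships = length(unique(d$sibship_id)),
                    n_discordant = n_disc,
                    b_between = between$estimate,
                    se_between = between$se,
                    b_within = w$estimate,
                    se_within = w$se,
                    pct_change = attenuation_pct(between$estimate,
                                                 w$estimate),
                    p_compare = cmp$p_wald,
                    p_compare_fdr = NA_real_,
                    stringsAsFactors = FALSE)
  attr(res, "within") <- w
  attr(res, "between") <- between
  attr(res, "comparison") <- cmp
  res
}
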