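#' Model specification for a PGS-outcome association
#'
#' @param outcome outcome column name.
#' @param link "logit" for binary outcomes (odds ratios) or "identity" for
#'   continuous outcomes (standardized betas).
#' @param exposure exposure column (the polygenic score), z-scored within
#'   the analysis sample.
#' @param covariates character vector of covariate terms; `a:b` denotes an
#'   interaction (e.g. the chip-by-PC terms `"chip:PC1"`).
#' @param cluster clustering column for the sandwich variance (family id).
#' @param filter optional function(data) returning a logical keep vector
#'   (e.g. excluding self-reported ADHD for sensitivity reruns).
#' @param min_n minimum complete-case sample size (default 50).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(outcome, link = c("identity", "logit"),
                       exposure = "PGS",
                       covariates = character(0),
                       cluster = "family_id",
                       filter = NULL, min_n = 50) {
  link <- match.arg(link)
  stopifnot(is.character(outcome), length(outcome) == 1,
            is.character(exposure), length(exposure) == 1,
            is.character(cluster), length(cluster) == 1)
  if (exposure %in% covariates) {
    stop("exposure must appear exactly once (not also in covariates)")
  }
  structure(list(outcome = outcome, link = link, exposure = exposure,
                 covariates = covariates, cluster = cluster,
                 filter = filter, min_n = min_n),
            class = "model_spec")
}

#' Fit a GLM by least squares or IRLS
#'
#' Identity link: ordinary least squares. Logit link: iteratively reweighted
#' least squares run to gradient norm < 1e-8 (at most 100 iterations).
#' Collinear columns are dropped via the QR decomposition with a warning.
#' A diverging coefficient (|beta| > 15 on the logit scale) marks the fit as
#' non-estimable (perfect separation).
#'
#' @param y response vector (0/1 for logit).
#' @param X design matrix including the intercept column.
#' @param link "identity" or "logit".
#' @return object of class `sibscore_glm`: coefficients, bread matrix,
#'   fitted values, log-likelihood, convergence and separation flags.
#' @export
fit_glm <- function(y, X, link = c("identity", "logit")) {
  link <- match.arg(link)
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping ", ncol(X) - qrX$rank, " collinear column(s): ",
            paste(colnames(X)[-keep], collapse = ", "), call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  if (link == "identity") {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    mu <- as.vector(X %*% beta)
    rss <- sum((y - mu)^2)
    s2 <- rss / n
    ll <- -n / 2 * (log(2 * pi * s2) + 1)
    bread <- chol2inv(chol(crossprod(X)))
    out <- list(coef = beta, bread = bread, fitted = mu, ll = ll,
                X = X, y = y, link = link, converged = TRUE,
                non_estimable = FALSE, n = n, rss = rss)
  } else {
    if (!all(y %in% c(0, 1))) stop("logit link requires a 0/1 response")
    beta <- rep(0, p)
    converged <- FALSE
    for (it in seq_len(100)) {
      eta <- as.vector(X %*% beta)
      mu <- stats::plogis(eta)
      g <- crossprod(X, y - mu)
      if (max(abs(g)) < 1e-8) { converged <- TRUE; break }
      w <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(X * w, X)
      beta <- beta + solve(H, g)
    }
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    ll <- sum(y * eta - log1p(exp(eta)))
    w <- pmax(mu * (1 - mu), 1e-10)
    bread <- solve(crossprod(X * w, X))
    out <- list(coef = stats::setNames(as.vector(beta), colnames(X)),
                bread = bread, fitted = mu, ll = ll, X = X, y = y,
                link = link, converged = converged,
                non_estimable = any(abs(beta) > 15), n = n)
  }
  class(out) <- "sibscore_glm"
  out
}

#' Cluster-robust (sandwich) covariance and standard errors
#'
#' Computes B^{-1} M B^{-1} with B the bread (information) and M the sum
#' over clusters of outer products of within-cluster score sums, with the
#' finite-cluster correction G/(G-1).
#'
#' @param fit a `sibscore_glm`.
#' @param cluster cluster id vector aligned with the fitted rows.
#' @return list with `vcov` and `se` (named as the coefficients).
#' @export
sandwich_se <- function(fit, cluster) {
  stopifnot(length(cluster) == fit$n)
  G <- length(unique(cluster))
  if (G < 2) stop("sandwich estimator needs at least 2 clusters")
  resid <- fit$y - fit$fitted
  U <- fit$X * resid               # estimating-equation scores
  S <- rowsum(U, group = cluster)
  meat <- crossprod(S)
  B <- fit$bread
  V <- (G / (G - 1)) * B %*% meat %*% B
  dimnames(V) <- list(names(fit$coef), names(fit$coef))
  list(vcov = V, se = sqrt(diag(V)))
}

#' Nagelkerke delta-R2 (logit) or R2 difference (identity)
#'
#' For logit models, Nagelkerke R2 of a fit is
#' `(1 - exp(2 (ll0 - ll) / n)) / (1 - exp(2 ll0 / n))` with `ll0` the
#' intercept-only log-likelihood; the reported value is R2(full model
#' including the exposure) minus R2(covariates-only model). For identity
#' models the difference of coefficients of determination is returned.
#'
#' @param fit_full fit including the exposure.
#' @param fit_null same model without the exposure.
#' @return delta-R2 (non-negative up to numerical noise).
#' @export
nagelkerke_delta_r2 <- function(fit_full, fit_null) {
  if (fit_full$n != fit_null$n || fit_full$link != fit_null$link) {
    stop("full and null fits must share sample and link")
  }
  if (!all(colnames(fit_null$X) %in% colnames(fit_full$X))) {
    stop("null model is not nested in the full model")
  }
  n <- fit_full$n
  if (fit_full$link == "identity") {
    tss <- sum((fit_full$y - mean(fit_full$y))^2)
    r2 <- function(f) 1 - f$rss / tss
    return(r2(fit_full) - r2(fit_null))
  }
  f0 <- fit_glm(fit_full$y,
                matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                link = "logit")
  ll0 <- f0$ll
  nag <- function(ll) {
    (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n))
  }
  nag(fit_full$ll) - nag(fit_null$ll)
}

## drop covariate terms that are constant in the analysis sample (and any
## interaction touching one); returns the reduced term vector
prune_constant_terms <- function(terms, data) {
  const <- function(v) {
    u <- unique(v[!is.na(v)])
    length(u) < 2
  }
  keep <- vapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    !any(vapply(parts, function(p) const(data[[p]]), logical(1)))
  }, logical(1))
  terms[keep]
}

term_columns <- function(terms) {
  unique(unlist(strsplit(terms, ":", fixed = TRUE)))
}

#' Run one PGS-outcome association model
#'
#' Complete-case GLM of the outcome on the z-scored exposure plus
#' covariates, family-clustered sandwich standard errors, Wald 95\%
#' confidence intervals and Nagelkerke (logit) or plain (identity) delta-R2
#' for the exposure. Continuous outcomes are z-scored within the analysis
#' sample, so identity-link estimates are standardized betas.
#'
#' @param spec a [model_spec()].
#' @param data phenotype/covariate data.frame containing outcome, exposure,
#'   covariates and the cluster column.
#' @param model_label label stored in the `model` column of the result.
#' @return one-row data.frame (class `assoc_result`) with columns outcome,
#'   model, n, estimate, se, ci_low, ci_high, p, p_fdr (NA until
#'   [bh_fdr()]), r2_delta, and for logit models `or`, `or_low`, `or_high`.
#' @export
run_association <- function(spec, data, model_label = "main") {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(spec$filter)) data <- data[spec$filter(data), , drop = FALSE]
  used <- unique(c(spec$outcome, spec$exposure,
                   term_columns(spec$covariates), spec$cluster))
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("data missing column(s): ",
                         paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  if (nrow(d) < spec$min_n) {
    stop("only ", nrow(d), " complete cases for outcome '", spec$outcome,
         "' (minimum ", spec$min_n, ")")
  }
  covs <- prune_constant_terms(spec$covariates, d)
  d$.exposure <- zscore(d[[spec$exposure]])
  y <- d[[spec$outcome]]
  if (spec$link == "identity") y <- zscore(y)
  f <- stats::reformulate(c(".exposure", covs))
  X <- stats::model.matrix(f, data = d)
  fit <- fit_glm(y, X, spec$link)
  Xnull <- stats::model.matrix(stats::reformulate(c("1", covs)), data = d)
  fit_null <- fit_glm(y, Xnull, spec$link)
  sw <- sandwich_se(fit, d[[spec$cluster]])
  est <- fit$coef[".exposure"]
  se <- sw$se[".exposure"]
  r2d <- nagelkerke_delta_r2(fit, fit_null)
  res <- data.frame(outcome = spec$outcome, model = model_label,
                    n = nrow(d), estimate = unname(est), se = unname(se),
                    ci_low = unname(est - 1.96 * se),
                    ci_high = unname(est + 1.96 * se),
                    p = unname(2 * stats::pnorm(-abs(est / se))),
                    p_fdr = NA_real_, r2_delta = r2d,
                    stringsAsFactors = FALSE)
  if (spec$link == "logit") {
    res$or <- exp(res$estimate)
    res$or_low <- exp(res$ci_low)
    res$or_high <- exp(res$ci_high)
  }
  if (fit$non_estimable) {
    res$estimate <- res$se <- res$ci_low <- res$ci_high <- res$p <- NA_real_
    res$model <- paste0(model_label, ":non_estimable")
    warning("possible perfect separation for outcome '", spec$outcome,
            "'; reported as non-estimable", call. = FALSE)
  }
  attr(res, "fit") <- fit
  attr(res, "vcov") <- sw$vcov
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Test moderation of the PGS effect by an interaction term
#'
#' Adds `exposure x moderator` (with the moderator main effect) to the
#' model of [run_association()] and reports the interaction coefficient
#' with its cluster-robust standard error.
#'
#' @param spec a [model_spec()].
#' @param data data.frame.
#' @param moderator moderator column name (binary or continuous; must vary).
#' @return one-row data.frame with the interaction estimate, sandwich SE,
#'   CI and p.
#' @export
run_interaction <- function(spec, data, moderator) {
  if (!is.null(spec$filter)) data <- data[spec$filter(data), , drop = FALSE]
  used <- unique(c(spec$outcome, spec$exposure, moderator,
                   term_columns(spec$covariates), spec$cluster))
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  mv <- d[[moderator]]
  if (length(unique(mv[!is.na(mv)])) < 2) {
    stop("moderator '", moderator, "' is constant")
  }
  covs <- prune_constant_terms(spec$covariates, d)
  d$.exposure <- zscore(d[[spec$exposure]])
  y <- d[[spec$outcome]]
  if (spec$link == "identity") y <- zscore(y)
  f <- stats::reformulate(c(".exposure", moderator,
                            paste0(".exposure:", moderator), covs))
  X <- stats::model.matrix(f, data = d)
  fit <- fit_glm(y, X, spec$link)
  sw <- sandwich_se(fit, d[[spec$cluster]])
  ia <- grep(paste0("^\\.exposure:"), names(fit$coef))
  est <- fit$coef[ia]; se <- sw$se[ia]
  data.frame(outcome = spec$outcome,
             model = paste0("interaction:", moderator),
             term = names(fit$coef)[ia], n = nrow(d),
             estimate = unname(est), se = unname(se),
             ci_low = unname(est - 1.96 * se),
             ci_high = unname(est + 1.96 * se),
             p = unname(2 * stats::pnorm(-abs(est / se))),
             stringsAsFactors = FALSE)
}

#' Stratified association analyses
#'
#' Refits the model of [run_association()] independently within each
#' stratum. The conventional splits are age (younger < 60, older >= 60),
#' sex, and educational attainment (low/high from [map_education()]).
#'
#' @param spec a [model_spec()].
#' @param data data.frame.
#' @param strata factor/character vector aligned with `data` rows (or a
#'   column name) defining the strata.
#' @return data.frame of per-stratum results; empty strata are skipped with
#'   a warning.
#' @export
run_stratified <- function(spec, data, strata) {
  if (is.character(strata) && length(strata) == 1) {
    strata <- data[[strata]]
  }
  stopifnot(length(strata) == nrow(data))
  out <- list()
  for (s in unique(strata[!is.na(strata)])) {
    d <- data[!is.na(strata) & strata == s, , drop = FALSE]
    r <- tryCatch(
      run_association(spec, d, model_label = paste0("stratum:", s)),
      error = function(e) {
        warning("stratum '", s, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(r)) out[[as.character(s)]] <- r
  }
  do.call(rbind, out)
}

#' Age strata at the 60-year boundary
#'
#' "older" means age >= 60 (a 60-year-old is in the older stratum).
#'
#' @param age numeric vector of ages.
#' @return character vector "younger"/"older".
#' @export
age_stratum <- function(age) {
  ifelse(is.na(age), NA_character_,
         ifelse(age >= 60, "older", "younger"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment over the whole test family, with the input order
#' restored (delegates to [stats::p.adjust()] after validation).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
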