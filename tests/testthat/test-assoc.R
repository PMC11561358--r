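test_that("logistic slope matches the 2x2 closed-form odds ratio", {
  ## exposed: 30 cases / 20 controls; unexposed: 10 cases / 40 controls
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  f <- fit_glm(y, cbind("(Intercept)" = 1, x = x), "logit")
  expect_equal(unname(f$coef["x"]), log(6), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("identity link reproduces exact linear data with zero residuals", {
  x <- seq(-2, 2, length.out = 50)
  y <- 1.5 - 0.7 * x
  f <- fit_glm(y, cbind("(Intercept)" = 1, x = x), "identity")
  expect_lt(max(abs(f$y - f$fitted)), 1e-12)
})

test_that("fit_glm agrees with the reference implementation on random data", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 150
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4), runif(n))
    colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
    yb <- rbinom(n, 1, plogis(0.2 + 0.6 * X[, 2] - 0.4 * X[, 3]))
    f <- fit_glm(yb, X, "logit")
    ref <- stats::glm(yb ~ X[, 2] + X[, 3] + X[, 4], family = binomial)
    expect_equal(unname(f$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(f$ll, as.numeric(logLik(ref)), tolerance = 1e-8)
    yc <- 0.5 * X[, 2] + rnorm(n)
    fc <- fit_glm(yc, X, "identity")
    refc <- stats::lm(yc ~ X[, 2] + X[, 3] + X[, 4])
    expect_equal(unname(fc$coef), unname(coef(refc)), tolerance = 1e-8)
  }
})

test_that("perfect separation is flagged as non-estimable", {
  x <- c(rep(0, 8), rep(1, 8))
  f <- fit_glm(x, cbind("(Intercept)" = 1, x = x), "logit")
  expect_true(f$non_estimable)
})

test_that("collinear columns are dropped with a warning", {
  set.seed(5)
  x <- rnorm(60)
  X <- cbind("(Intercept)" = 1, a = x, b = 2 * x)
  expect_warning(f <- fit_glm(rnorm(60), X, "identity"), "collinear")
  expect_equal(length(f$coef), 2)
})

test_that("cluster sandwich reduces to HC0-type robust SEs and is invariant
           to cluster duplication", {
  set.seed(11)
  n <- 120
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- 0.4 * X[, 2] + rnorm(n) * (1 + 0.5 * abs(X[, 2]))
  f <- fit_glm(y, X, "identity")
  ## every sample its own cluster: equals HC0 up to n/(n-1)
  sw <- sandwich_se(f, seq_len(n))
  u <- (y - f$fitted)
  hc0 <- f$bread %*% crossprod(X * u) %*% f$bread
  expect_equal(unname(sw$vcov), unname(hc0 * n / (n - 1)),
               tolerance = 1e-10)
  ## duplicating every cluster leaves the coefficients unchanged
  f2 <- fit_glm(c(y, y), rbind(X, X), "identity")
  expect_equal(f2$coef, f$coef, tolerance = 1e-10)
  expect_error(sandwich_se(f, rep(1, n)), "2 clusters")
})

test_that("sandwich covariance matches the sandwich package on clustered fits", {
  skip_if_not_installed("sandwich")
  set.seed(12)
  n <- 200
  cl <- sample(1:40, n, replace = TRUE)
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.3))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- rbinom(n, 1, plogis(0.3 * X[, 2]))
  f <- fit_glm(y, X, "logit")
  ref <- stats::glm(y ~ X[, 2] + X[, 3], family = binomial)
  V <- sandwich::vcovCL(ref, cluster = cl, type = "HC0", cadjust = TRUE)
  sw <- sandwich_se(f, cl)
  expect_equal(unname(sw$vcov), unname(V), tolerance = 1e-5)
})

test_that("Nagelkerke delta-R2 matches an independent likelihood evaluation", {
  ## 6-observation instance, oracle likelihood via glm + dbinom
  y <- c(1, 0, 1, 0, 1, 0)
  x <- c(2, 1, 3, 2, 0, 2)
  X <- cbind("(Intercept)" = 1, x = x)
  f_full <- fit_glm(y, X, "logit")
  f_null <- fit_glm(y, X[, 1, drop = FALSE], "logit")
  got <- nagelkerke_delta_r2(f_full, f_null)
  n <- 6
  ll <- function(fit) sum(stats::dbinom(y, 1, fitted(fit), log = TRUE))
  l1 <- ll(stats::glm(y ~ x, family = binomial))
  l0 <- ll(stats::glm(y ~ 1, family = binomial))
  nag <- function(l) (1 - exp(2 * (l0 - l) / n)) / (1 - exp(2 * l0 / n))
  expect_equal(got, nag(l1) - nag(l0), tolerance = 1e-10)

  ## identity link: orthogonal standardized exposure contributes ~b^2
  set.seed(13)
  n2 <- 20000
  x2 <- rnorm(n2); w <- rnorm(n2)
  y2 <- 0.3 * x2 + 0.5 * w + rnorm(n2, 0, sqrt(1 - 0.09 - 0.25))
  y2 <- as.vector(scale(y2))
  Xf <- cbind("(Intercept)" = 1, x = x2, w = w)
  ff <- fit_glm(y2, Xf, "identity")
  fn <- fit_glm(y2, Xf[, c(1, 3)], "identity")
  expect_lt(abs(nagelkerke_delta_r2(ff, fn) - 0.09), 0.01)

  ## null exposure: delta-R2 is tiny
  y3 <- rbinom(5000, 1, 0.3)
  Xr <- cbind("(Intercept)" = 1, x = rnorm(5000))
  d0 <- nagelkerke_delta_r2(fit_glm(y3, Xr, "logit"),
                            fit_glm(y3, Xr[, 1, drop = FALSE], "logit"))
  expect_lt(d0, 0.001)
  expect_gte(d0, -1e-12)
  expect_error(nagelkerke_delta_r2(ff, fit_glm(y2[-1], Xf[-1, ],
                                               "identity")),
               "share")
})

test_that("run_association recovers simulated effects and the inflation law", {
  cfg <- sim_config(n_families = 2500, sibs_per_family = 2,
                    n_variants = 80, beta_direct = 0.2, beta_nurture = 0,
                    within_block_rho = 0, seed = 71)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  ph$PGS <- co$truth$pgs_true[ph$individual_id]
  spec <- model_spec("biomarker", "identity",
                     covariates = c("age", "sex"))
  r <- run_association(spec, ph)
  ## direct effect on the standardized-outcome scale
  expect_lt(abs(r$estimate - 0.2 / sd(ph$biomarker)), 3 * r$se)

  cfg2 <- sim_config(n_families = 2500, sibs_per_family = 2,
                     n_variants = 80, beta_direct = 0.2,
                     beta_nurture = 0.2, var_noise = 0.83,
                     within_block_rho = 0, seed = 72)
  co2 <- simulate_cohort(cfg2)
  ph2 <- co2$phenotypes
  ph2$PGS <- co2$truth$pgs_true[ph2$individual_id]
  r2 <- run_association(spec, ph2)
  ## population slope inflates to beta_direct + beta_nurture/2
  expect_lt(abs(r2$estimate - 0.3 / sd(ph2$biomarker)), 3 * r2$se)

  expect_error(run_association(spec, ph[1:30, ]), "complete cases")
})

test_that("degenerate chip covariate leaves the exposure estimate unchanged", {
  cfg <- sim_config(n_families = 300, n_variants = 50,
                    disease_prevalence = c(metabolic_disease = 0.3),
                    seed = 73)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  ph$PGS <- co$truth$pgs_true[ph$individual_id]
  ph$chip <- "GSA"    # constant chip
  pcs <- paste0("PC", 1:4)
  s_plain <- model_spec("biomarker", "identity",
                        covariates = c("age", "sex", pcs))
  s_chip <- model_spec("biomarker", "identity",
                       covariates = c("age", "sex", "chip", pcs,
                                      paste0("chip:", pcs)))
  expect_equal(run_association(s_chip, ph)$estimate,
               run_association(s_plain, ph)$estimate, tolerance = 1e-12)
})

test_that("random exclusion flags barely move the estimate", {
  cfg <- sim_config(n_families = 1500, n_variants = 60,
                    within_block_rho = 0, seed = 74)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  ph$PGS <- co$truth$pgs_true[ph$individual_id]
  set.seed(75)
  ph$flag <- rbinom(nrow(ph), 1, 0.1)
  spec <- model_spec("biomarker", "identity",
                     covariates = c("age", "sex"))
  spec_ex <- spec
  spec_ex$filter <- function(d) d$flag == 0
  r_all <- run_association(spec, ph)
  r_ex <- run_association(spec_ex, ph)
  expect_lt(abs(r_all$estimate - r_ex$estimate),
            sqrt(r_all$se^2 + r_ex$se^2))
})

test_that("BMI adjustment removes a fully BMI-mediated PGS effect", {
  set.seed(76)
  n <- 4000
  d <- data.frame(family_id = rep(1:(n / 2), each = 2),
                  PGS = rnorm(n), age = rnorm(n, 45, 10),
                  sex = rbinom(n, 1, 0.5) + 1)
  d$bmi <- 0.5 * d$PGS + rnorm(n, 0, 0.2)   # PGS acts only through BMI
  d$y <- 0.6 * d$bmi + rnorm(n, 0, 0.5)
  s0 <- model_spec("y", "identity", covariates = c("age", "sex"))
  s1 <- model_spec("y", "identity", covariates = c("age", "sex", "bmi"))
  b0 <- run_association(s0, d)$estimate
  b1 <- run_association(s1, d)$estimate
  expect_gt(1 - abs(b1) / abs(b0), 0.8)
})

test_that("interaction models recover stratum slope differences", {
  set.seed(77)
  n <- 6000
  d <- data.frame(family_id = rep(1:(n / 2), each = 2),
                  PGS = rnorm(n), grp = rbinom(n, 1, 0.5),
                  age = rnorm(n, 45, 10), sex = rbinom(n, 1, 0.5) + 1)
  ## equal slopes: interaction ~ 0
  d$y_eq <- 0.2 * d$PGS + rnorm(n)
  s <- model_spec("y_eq", "identity", covariates = c("age", "sex"))
  i_eq <- run_interaction(s, d, "grp")
  expect_lt(abs(i_eq$estimate), 3 * i_eq$se)
  ## slopes 0.1 vs 0.3: interaction ~ 0.2
  d$y_dif <- (0.1 + 0.2 * d$grp) * d$PGS + rnorm(n)
  s2 <- model_spec("y_dif", "identity", covariates = c("age", "sex"))
  i_dif <- run_interaction(s2, d, "grp")
  expect_lt(abs(i_dif$estimate - 0.2), 3 * i_dif$se)
  ## constant moderator is rejected
  d$konst <- 1
  expect_error(run_interaction(s2, d, "konst"), "constant")

  ## stratified estimates are jointly consistent with the interaction
  strat <- run_stratified(s2, d, ifelse(d$grp == 1, "g1", "g0"))
  b1 <- strat$estimate[strat$model == "stratum:g1"]
  b0 <- strat$estimate[strat$model == "stratum:g0"]
  se1 <- strat$se[strat$model == "stratum:g1"]
  se0 <- strat$se[strat$model == "stratum:g0"]
  ## compare on the unstandardized-outcome scale is not available here, so
  ## allow the standardization discrepancy plus 3 joint SEs
  expect_lt(abs((b1 - b0) - i_dif$estimate),
            3 * sqrt(se1^2 + se0^2 + i_dif$se^2) + 0.05)
})

test_that("age stratification puts 60-year-olds in the older stratum", {
  expect_identical(age_stratum(c(59.9, 60, 60.1, NA)),
                   c("younger", "older", "older", NA))
})

test_that("empty strata are skipped with a warning", {
  cfg <- sim_config(n_families = 200, n_variants = 40,
                    disease_prevalence = c(metabolic_disease = 0.3),
                    seed = 78)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  ph$PGS <- co$truth$pgs_true[ph$individual_id]
  spec <- model_spec("biomarker", "identity",
                     covariates = c("age", "sex"))
  grp <- rep("all", nrow(ph)); grp[1] <- "tiny"
  expect_warning(out <- run_stratified(spec, ph, grp), "skipped")
  expect_equal(nrow(out), 1)
})

test_that("BH adjustment equals the literal step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  set.seed(79)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("a permuted exposure is null-calibrated", {
  set.seed(80)
  n <- 400
  hits <- vapply(1:200, function(r) {
    d <- data.frame(family_id = rep(1:(n / 2), each = 2),
                    PGS = rnorm(n), age = rnorm(n, 45, 10),
                    sex = rbinom(n, 1, 0.5) + 1)
    d$y <- rnorm(n)
    rr <- run_association(
      model_spec("y", "identity", covariates = c("age", "sex")), d)
    abs(rr$estimate) < 3 * rr$se
  }, logical(1))
  expect_gte(mean(hits), 0.94)
})
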