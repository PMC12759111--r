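make_lmm_data <- function(n_subjects = 135, beta_age = 0.002, sd_b0 = 0.02,
                          sd_b1 = 0.004, sd_e = 0.005, seed = 1) {
  sheet <- make_sheet(n_subjects, seed = seed)
  d <- longitudinal_design(sheet, covariates = "sex")
  agec <- d$data$age - d$age_center
  sub <- rep(seq_len(n_subjects), each = 3)
  b0 <- rnorm(n_subjects, 0, sd_b0)
  b1 <- rnorm(n_subjects, 0, sd_b1)
  y <- 0.5 + beta_age * agec + 0.01 * d$data$sex +
    b0[sub] + b1[sub] * agec + rnorm(3 * n_subjects, 0, sd_e)
  list(design = d, y = y, b0 = b0, b1 = b1, agec = agec)
}

test_that("constant response pins all variance components at the boundary", {
  sheet <- make_sheet(20, seed = 2)
  d <- longitudinal_design(sheet, covariates = "sex")
  f <- fit_lmm(d, rep(0.5, d$n), "intercept_only")
  expect_equal(unname(f$beta[["(Intercept)"]]), 0.5, tolerance = 1e-8)
  expect_lt(abs(f$beta[["age"]]), 1e-8)
  expect_lt(f$sigma2, 1e-8)
  expect_lt(max(abs(f$Psi)), 1e-8)
})

test_that("ML recovers the generating parameters and the exact likelihood", {
  dat <- make_lmm_data(500, seed = 8)
  f2 <- fit_lmm(dat$design, dat$y, "intercept_slope")
  expect_true(f2$converged)
  expect_lt(abs(f2$beta[["age"]] / 0.002 - 1), 0.15)
  expect_lt(abs(f2$Psi["(Intercept)", "(Intercept)"] / 0.02^2 - 1), 0.15)
  expect_lt(abs(f2$Psi["age", "age"] / 0.004^2 - 1), 0.15)
  expect_lt(abs(f2$sigma2 / 0.005^2 - 1), 0.15)

  # independent per-subject multivariate-normal evaluation of the marginal
  # log-likelihood at the returned parameters
  expect_lt(abs(f2$logLik - mvn_loglik_oracle(f2, dat$design, dat$y)), 1e-6)
  f1 <- fit_lmm(dat$design, dat$y, "intercept_only")
  expect_lt(abs(f1$logLik - mvn_loglik_oracle(f1, dat$design, dat$y)), 1e-6)
  expect_gte(f2$logLik, f1$logLik - 1e-6)

  # AIC bookkeeping: 2k - 2l with k = p_fixed + 2 resp. + 4
  expect_equal(f1$AIC, 2 * (f1$p_fixed + 2) - 2 * f1$logLik)
  expect_equal(f2$AIC, 2 * (f2$p_fixed + 4) - 2 * f2$logLik)

  # BLUPs of each random effect average to ~0 on a balanced design
  expect_lt(abs(mean(f2$blups$b0)), 1e-6 * sd(f2$blups$b0))
  expect_lt(abs(mean(f2$blups$b1)), 1e-6 * sd(f2$blups$b1))
})

test_that("fits agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  dat <- make_lmm_data(120, seed = 15)
  d <- dat$design
  dd <- d$data
  dd$agec <- dd$age - d$age_center
  dd$y <- dat$y
  f1 <- fit_lmm(d, dat$y, "intercept_only")
  f2 <- fit_lmm(d, dat$y, "intercept_slope")
  l1 <- lme4::lmer(y ~ agec + sex + (1 | subject_id), dd, REML = FALSE)
  l2 <- lme4::lmer(y ~ agec + sex + (agec | subject_id), dd, REML = FALSE)
  expect_equal(f1$logLik, as.numeric(stats::logLik(l1)), tolerance = 1e-6)
  expect_equal(f2$logLik, as.numeric(stats::logLik(l2)), tolerance = 1e-6)
  expect_equal(unname(f2$beta[["age"]]),
               unname(lme4::fixef(l2)[["agec"]]), tolerance = 1e-5)
  expect_gt(cor(f2$blups$b1, lme4::ranef(l2)$subject_id$agec), 0.99999)
})

test_that("pinning the slope block to zero reproduces the intercept-only fit", {
  dat <- make_lmm_data(60, sd_b1 = 0, seed = 4)
  d <- dat$design
  f1 <- fit_lmm(d, dat$y, "intercept_only")
  prob <- methylpace:::lmm_problem_cpp(d$X, d$Z, dat$y, d$starts0, d$ends0)
  dev_pinned <- methylpace:::lmm_deviance_cpp(c(f1$theta, 0, 0), prob, FALSE)
  expect_lt(abs(-0.5 * dev_pinned - f1$logLik), 1e-8)
})

test_that("estimates are invariant to observation-row reordering", {
  dat <- make_lmm_data(50, seed = 6)
  d <- dat$design
  set.seed(99)
  perm <- sample(d$n)
  d2 <- longitudinal_design(d$data[perm, ], covariates = "sex")
  y_by_id <- setNames(dat$y, d$sample_ids)
  f <- fit_lmm(d, dat$y, "intercept_slope")
  f2 <- fit_lmm(d2, y_by_id[d2$sample_ids], "intercept_slope")
  expect_equal(f$beta[["age"]], f2$beta[["age"]], tolerance = 1e-6)
  expect_equal(f$sigma2, f2$sigma2, tolerance = 1e-6)
  expect_equal(f$Psi, f2$Psi, tolerance = 1e-6)
})

test_that("BLUP slopes track true slopes on nearly noise-free balanced data", {
  n <- 80
  sheet <- make_sheet(n, seed = 12)
  sheet$age <- rep(c(70, 72.5, 75), n)  # fully balanced ages
  d <- longitudinal_design(sheet, covariates = "sex")
  agec <- d$data$age - d$age_center
  sub <- rep(seq_len(n), each = 3)
  b1 <- rnorm(n, 0, 0.01)
  y <- 0.4 + b1[sub] * agec + rnorm(3 * n, 0, 1e-5)
  f <- fit_lmm(d, y, "intercept_slope")
  ord <- match(d$subjects, sheet$subject_id[seq(1, 3 * n, by = 3)])
  expect_gt(cor(f$blups$b1, b1[ord]), 0.999)
})

test_that("boundary-mixture LRT arithmetic follows the chi-square mixture", {
  dat <- make_lmm_data(40, sd_b1 = 0, seed = 3)
  f1 <- fit_lmm(dat$design, dat$y, "intercept_only")
  f2 <- fit_lmm(dat$design, dat$y, "intercept_slope", init = f1$theta)
  st <- lrt_random_slope(f1, f2)
  expect_gte(st$lambda, 0)
  expect_equal(st$p_value,
               0.5 * pchisq(st$lambda, 1, lower.tail = FALSE) +
                 0.5 * pchisq(st$lambda, 2, lower.tail = FALSE))
  expect_equal(st$delta_aic, f1$AIC - f2$AIC)

  # frozen closed-form checks of the mixture tail
  mix <- function(l) 0.5 * pchisq(l, 1, lower.tail = FALSE) +
    0.5 * pchisq(l, 2, lower.tail = FALSE)
  expect_equal(mix(0), 1)
  expect_equal(mix(5), 0.05371614, tolerance = 1e-6)

  # mismatched designs are refused
  other <- make_lmm_data(41, seed = 5)
  f2b <- fit_lmm(other$design, other$y, "intercept_slope")
  expect_error(lrt_random_slope(f1, f2b), "mismatched")
})

test_that("Wald p-value follows the standard-normal reference", {
  dat <- make_lmm_data(60, beta_age = 0.01, seed = 10)
  f <- fit_lmm(dat$design, dat$y, "intercept_slope")
  z <- f$beta[["age"]] / f$se[["age"]]
  expect_equal(wald_age_p(f), 2 * pnorm(-abs(z)))
  f0 <- f
  f0$beta[["age"]] <- 0
  expect_equal(wald_age_p(f0), 1)
  f196 <- f
  f196$beta[["age"]] <- 1.96
  f196$se[["age"]] <- 1
  expect_equal(wald_age_p(f196), 0.04999579, tolerance = 1e-6)
  f0$se[["age"]] <- 0
  expect_error(wald_age_p(f0), "degenerate")
})

test_that("degenerate designs and misaligned responses are rejected", {
  sheet <- make_sheet(10, seed = 1)
  sheet$flat <- 1
  expect_error(longitudinal_design(sheet, covariates = c("sex", "flat")),
               "degenerate design")
  d <- longitudinal_design(sheet, covariates = "sex")
  expect_error(fit_lmm(d, rnorm(5), "intercept_only"), "length")
})
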