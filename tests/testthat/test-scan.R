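strong_cohort <- function(n_cpgs, fractions, seed) {
  sig_e <- 0.005
  span_ss <- sum((c(0, 2.5, 5) - 2.5)^2)      # per-subject age sum of squares
  cohort_config(
    n_subjects = 135, n_cpgs = n_cpgs, class_fractions = fractions,
    beta_age_mean = 5 * sig_e / 5,            # 5 sigma_e over the age span
    slope_sd = 2 * sig_e / sqrt(span_ss),     # 2x the subject-slope SE
    residual_sd = sig_e, seed = seed)
}

test_that("Bonferroni threshold and calls bookkeeping", {
  coh <- simulate_cohort(strong_cohort(
    20, c(null = 0.5, age_associated = 0.25, age_varying = 0.25, both = 0), 2))
  d <- longitudinal_design(coh$sample_sheet)
  calls <- classify_cpgs(coh$meth, d, family_alpha = 0.05)
  expect_equal(unique(calls$threshold), 0.05 / 20)
  expect_equal(attr(calls, "M"), 20L)
  expect_equal(sum(table(calls$category)) + attr(calls, "n_excluded"), 20)
  expect_error(classify_cpgs(unname(coh$meth), d), "sample ids")
})

test_that("planted classes are recovered with high sensitivity and low FDP", {
  coh <- simulate_cohort(strong_cohort(
    80, c(null = 0.25, age_associated = 0.25, age_varying = 0.25, both = 0.25), 1))
  d <- longitudinal_design(coh$sample_sheet)
  calls <- classify_cpgs(coh$meth, d)
  truth <- coh$truth$cpg_class[calls$cpg]
  want <- c(null = "neither", age_associated = "age_associated",
            age_varying = "age_varying", both = "both")
  for (cl in names(want)) {
    called <- calls$category[truth == cl]
    expect_gte(mean(called == want[[cl]], na.rm = TRUE), 0.8)
    hits <- which(calls$category == want[[cl]])
    if (length(hits)) expect_lte(mean(truth[hits] != cl), 0.05)
  }

  # BLUP change rates track the planted subject slopes
  sl <- attr(calls, "slopes")
  tru <- coh$truth$true_subject_slopes[rownames(sl), ]
  av <- names(coh$truth$cpg_class)[coh$truth$cpg_class == "age_varying"]
  rc <- vapply(av, function(j) cor(sl[, j], tru[, j], method = "spearman"),
               numeric(1))
  expect_gt(median(rc), 0.7)

  # row-order invariance of the classification
  perm <- rev(seq_len(nrow(coh$meth)))
  calls2 <- classify_cpgs(coh$meth[perm, ], d)
  m <- match(calls$cpg, calls2$cpg)
  expect_identical(calls$category, calls2$category[m])

  # monotonicity in the family alpha
  calls_strict <- classify_cpgs(coh$meth, d, family_alpha = 0.001)
  for (cat in c("age_varying", "age_associated")) {
    n_loose <- sum(calls$category %in% c(cat, "both"), na.rm = TRUE)
    n_strict <- sum(calls_strict$category %in% c(cat, "both"), na.rm = TRUE)
    expect_gte(n_loose, n_strict)
  }

  # AIC criterion variant flags planted slope classes too
  calls_aic <- classify_cpgs(coh$meth, d, criterion = "aic")
  av_aic <- calls_aic$category %in% c("age_varying", "both")
  expect_gte(mean(av_aic[truth %in% c("age_varying", "both")], na.rm = TRUE), 0.8)
})

test_that("change_rates restricts the slope matrix to the requested calls", {
  coh <- simulate_cohort(strong_cohort(
    40, c(null = 0.5, age_associated = 0, age_varying = 0.5, both = 0), 5))
  d <- longitudinal_design(coh$sample_sheet)
  calls <- classify_cpgs(coh$meth, d)
  sl <- change_rates(calls)
  expect_true(all(colnames(sl) %in%
                    calls$cpg[calls$category %in% c("age_varying", "both")]))
  expect_equal(nrow(sl), 135)
})

test_that("PCA reproduces exact linear-algebra identities", {
  set.seed(31)
  # rank-1 matrix: first component carries all variance
  a <- rnorm(30)
  b <- rnorm(12)
  m1 <- a %o% b
  dimnames(m1) <- list(paste0("cg", 1:30), paste0("s", 1:12))
  p1 <- pca_scores(m1, 2)
  expect_equal(p1$ev_fraction[1], 1, tolerance = 1e-12)

  # full-rank reconstruction and unit-norm loadings
  m <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(paste0("cg", 1:30), paste0("s", 1:12)))
  pf <- pca_scores(m, 12)
  centered <- t(m) - colMeans(t(m))[col(t(m))]
  centered <- scale(t(m), center = TRUE, scale = FALSE)
  expect_lt(max(abs(pf$scores %*% t(pf$loadings) - centered)), 1e-8)
  expect_equal(unname(colSums(pf$loadings^2)), rep(1, 12), tolerance = 1e-10)
  expect_true(all(diff(pf$ev_fraction) < 1e-12))
  expect_lte(sum(pf$ev_fraction), 1 + 1e-12)

  # explained variance agrees with an independent eigendecomposition
  ev <- eigen(cov(t(m)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pf$ev_fraction[1:12], (ev / sum(ev))[1:12], tolerance = 1e-8)

  expect_error(pca_scores(m, 13), "n_components")
})

test_that("PC scores built from age show a fixed effect without slope variance", {
  sheet <- make_sheet(60, seed = 44)
  d <- longitudinal_design(sheet, covariates = "sex")
  agec <- d$data$age - d$age_center
  fake <- structure(list(
    scores = cbind(PC1 = agec + rnorm(d$n, 0, 0.05)),
    loadings = matrix(1, 1, 1), ev_fraction = 1), class = "methyl_pca")
  rownames(fake$scores) <- d$sample_ids
  res <- pc_age_association(fake, d)
  expect_lt(res$p_fixed, 1e-6)
  expect_gt(res$p_slope, 0.05)
  expect_equal(res$beta_age, 1, tolerance = 0.05)
})

test_that("loading contrast behaves under symmetry, planting and swaps", {
  mk_calls <- function(cpgs, category) {
    structure(data.frame(cpg = cpgs, category = category,
                         stringsAsFactors = FALSE),
              class = c("cpg_calls", "data.frame"))
  }
  set.seed(7)
  n <- 200
  cpgs <- paste0("cg", seq_len(2 * n))
  l2 <- abs(rnorm(2 * n, 0.1, 0.02))
  l1 <- c(2 * l2[1:n], l2[(n + 1):(2 * n)] * runif(n, 0.9, 1.1))
  loadings <- cbind(PC1 = l1, PC2 = l2)
  rownames(loadings) <- cpgs
  pca <- structure(list(scores = NULL, loadings = loadings,
                        ev_fraction = c(0.5, 0.3)), class = "methyl_pca")
  calls <- mk_calls(cpgs, rep(c("age_varying", "age_associated"), each = n))

  res <- loading_contrast(pca, calls)
  planted <- res[res$category == "age_varying", ]
  expect_gt(planted$median_diff, 0)
  expect_lt(planted$p, 0.01)

  # swapping the two loading columns flips the sign of the contrast
  pca_sw <- pca
  pca_sw$loadings <- pca$loadings[, c(2, 1)]
  res_sw <- loading_contrast(pca_sw, calls)
  expect_equal(res_sw$median_diff[res_sw$category == "age_varying"],
               -planted$median_diff)

  # identical absolute loadings: zero median difference, p = 1
  pca_eq <- pca
  pca_eq$loadings <- cbind(PC1 = l2, PC2 = -l2)
  rownames(pca_eq$loadings) <- cpgs
  res_eq <- loading_contrast(pca_eq, calls)
  expect_equal(res_eq$median_diff, c(0, 0))
  expect_equal(res_eq$p, c(1, 1))

  # undersized category reported as NA with a warning
  calls_small <- mk_calls(cpgs[1:5], rep("age_varying", 5))
  expect_warning(res_na <- loading_contrast(pca, calls_small,
                                            categories = "age_varying"),
                 "fewer than")
  expect_true(is.na(res_na$p))
})
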