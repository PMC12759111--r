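#' Two-step per-CpG classification: age-associated and age-varying sites
#'
#' For every CpG row, fits the random-intercept model (model 1) and the
#' random-intercept + random-slope model (model 2) by maximum likelihood,
#' then applies the two-step call:
#' \itemize{
#'   \item *age-varying*: the random-slope test rejects at the
#'     Bonferroni-corrected level `family_alpha / M` (boundary-mixture
#'     likelihood-ratio test by default, or `delta_aic > 0` when
#'     `criterion = "aic"`);
#'   \item *age-associated*: the Wald p-value of the fixed age effect, taken
#'     from the best model by AIC, is below `family_alpha / M`.
#' }
#' CpGs meeting both calls are labelled `both`; the remainder `neither`.
#' The family size `M` is the number of CpGs attempted (converged or not),
#' so the per-test threshold does not depend on convergence outcomes.
#' Model-2 random-slope BLUPs are kept as each subject's methylation change
#' rate (response units per year).
#'
#' @param meth CpG x sample matrix; column names must match the design's
#'   sample ids (columns are aligned by name).
#' @param design a [longitudinal_design()].
#' @param family_alpha family-wise error target for the Bonferroni split.
#' @param criterion `"lrt"` (mixture likelihood-ratio p with Bonferroni) or
#'   `"aic"` (model 2 wins by AIC) for the age-varying call.
#' @param force_model1_fixed take the fixed-effect p always from model 1
#'   instead of the best-AIC model.
#' @param verbose print progress every 500 CpGs.
#' @return object of class `cpg_calls`: data.frame with columns `cpg`,
#'   `category`, `lambda`, `p_slope`, `delta_aic`, `beta_age`, `p_fixed`,
#'   `threshold`, `converged`, `degenerate`; the subject x CpG matrix of
#'   slope BLUPs is in `attr(, "slopes")`.
#' @export
classify_cpgs <- function(meth, design, family_alpha = 0.05,
                          criterion = c("lrt", "aic"),
                          force_model1_fixed = FALSE, verbose = FALSE) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(design, "longitudinal_design"), is.matrix(meth))
  if (is.null(colnames(meth)) || !all(design$sample_ids %in% colnames(meth))) {
    stop("methylation matrix columns must be named by the design's sample ids")
  }
  meth <- meth[, design$sample_ids, drop = FALSE]
  cpgs <- rownames(meth)
  if (is.null(cpgs)) cpgs <- paste0("cpg", seq_len(nrow(meth)))
  M <- nrow(meth)
  threshold <- family_alpha / M

  res <- data.frame(
    cpg = cpgs, category = NA_character_, lambda = NA_real_,
    p_slope = NA_real_, delta_aic = NA_real_, beta_age = NA_real_,
    p_fixed = NA_real_, threshold = threshold, converged = FALSE,
    degenerate = FALSE, stringsAsFactors = FALSE
  )
  slopes <- matrix(NA_real_, design$n_subjects, M,
                   dimnames = list(design$subjects, cpgs))

  for (j in seq_len(M)) {
    y <- meth[j, ]
    if (stats::sd(y) < 1e-10) {
      res$degenerate[j] <- TRUE
      next
    }
    f1 <- fit_lmm(design, y, "intercept_only")
    f2 <- fit_lmm(design, y, "intercept_slope", init = f1$theta)
    st <- lrt_random_slope(f1, f2)
    best <- if (!force_model1_fixed && st$delta_aic > 0) f2 else f1
    res$lambda[j] <- st$lambda
    res$p_slope[j] <- st$p_value
    res$delta_aic[j] <- st$delta_aic
    res$beta_age[j] <- best$beta[["age"]]
    res$p_fixed[j] <- wald_age_p(best)
    res$converged[j] <- f2$converged
    slopes[, j] <- f2$blups$b1
    if (verbose && j %% 500 == 0) message("  classified ", j, "/", M, " CpGs")
  }

  ok <- res$converged & !res$degenerate
  av <- if (criterion == "lrt") res$p_slope < threshold else res$delta_aic > 0
  aa <- res$p_fixed < threshold
  res$category[ok] <- ifelse(av[ok] & aa[ok], "both",
                             ifelse(av[ok], "age_varying",
                                    ifelse(aa[ok], "age_associated", "neither")))
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(n_excluded, " CpG(s) excluded from category counts ",
            "(non-converged or degenerate)")
  }

  structure(res, slopes = slopes, alpha = family_alpha, criterion = criterion,
            M = M, n_excluded = n_excluded,
            class = c("cpg_calls", "data.frame"))
}

#' Extract the subject x CpG slope-BLUP matrix from a scan
#'
#' @param calls a [classify_cpgs()] result.
#' @param categories restrict to CpGs whose category is in this set
#'   (default: the age-varying sites, including the `both` overlap).
#' @return subject x CpG numeric matrix of per-year methylation change-rate
#'   deviations.
#' @export
change_rates <- function(calls, categories = c("age_varying", "both")) {
  stopifnot(inherits(calls, "cpg_calls"))
  sl <- attr(calls, "slopes")
  keep <- calls$cpg[!is.na(calls$category) & calls$category %in% categories]
  sl[, keep, drop = FALSE]
}

#' Principal component analysis of a methylation matrix
#'
#' PCA of samples over centred, unscaled beta-values (beta-values share a
#' common scale, so no variance scaling is applied). Components are oriented
#' so the loading of largest magnitude is positive.
#'
#' @param meth CpG x sample matrix.
#' @param n_components number of components to return.
#' @return object of class `methyl_pca`: `scores` (sample x component),
#'   `loadings` (CpG x component, unit columns), `ev_fraction`
#'   (explained-variance fractions for all components).
#' @export
pca_scores <- function(meth, n_components = 2) {
  stopifnot(is.matrix(meth))
  if (nrow(meth) < 2 || ncol(meth) < 2) stop("need >= 2 CpGs and >= 2 samples")
  maxc <- min(ncol(meth), nrow(meth))
  if (n_components > maxc) {
    stop("n_components (", n_components, ") exceeds min(dim) = ", maxc)
  }
  pr <- stats::prcomp(t(meth), center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, `*`)
  loadings <- sweep(pr$rotation, 2, flip, `*`)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = loadings, ev_fraction = ev,
                 center = pr$center),
            class = "methyl_pca")
}

#' @export
print.methyl_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat("methylation PCA:", nrow(x$scores), "samples,", k, "components kept\n")
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$ev_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Mixed-model association of principal components with age
#'
#' Fits the random-intercept + random-slope model to each component score
#' with full covariate adjustment, reporting the fixed age effect (does the
#' component track age on average?) and the random-slope test (does its age
#' trajectory vary across subjects?).
#'
#' @param pca a [pca_scores()] result.
#' @param design a [longitudinal_design()]; score rows are matched to the
#'   design by sample id.
#' @return data.frame: `component`, `beta_age`, `se`, `p_fixed`, `lambda`,
#'   `p_slope`, `delta_aic`.
#' @export
pc_age_association <- function(pca, design) {
  stopifnot(inherits(pca, "methyl_pca"), inherits(design, "longitudinal_design"))
  sc <- pca$scores
  if (!all(design$sample_ids %in% rownames(sc))) {
    stop("PCA scores do not cover the design's sample ids")
  }
  sc <- sc[design$sample_ids, , drop = FALSE]
  out <- lapply(seq_len(ncol(sc)), function(k) {
    f1 <- fit_lmm(design, sc[, k], "intercept_only")
    f2 <- fit_lmm(design, sc[, k], "intercept_slope", init = f1$theta)
    st <- lrt_random_slope(f1, f2)
    data.frame(component = colnames(sc)[k], beta_age = f2$beta[["age"]],
               se = f2$se[["age"]], p_fixed = wald_age_p(f2),
               lambda = st$lambda, p_slope = st$p_value,
               delta_aic = st$delta_aic, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Contrast of absolute PC1 vs PC2 loadings within CpG categories
#'
#' Within each CpG category, compares the absolute loadings on the first two
#' components by a paired two-sided Wilcoxon signed-rank test. A positive
#' median difference means the category loads more heavily on PC1.
#'
#' @param pca a [pca_scores()] result with >= 2 components.
#' @param calls a [classify_cpgs()] result.
#' @param categories category labels to contrast.
#' @param min_n categories with fewer CpGs are reported as `NA` with a
#'   warning.
#' @return data.frame: `category`, `n`, `median_diff` (|PC1| - |PC2|), `p`.
#' @export
loading_contrast <- function(pca, calls,
                             categories = c("age_associated", "age_varying"),
                             min_n = 10) {
  stopifnot(inherits(pca, "methyl_pca"), inherits(calls, "cpg_calls"))
  if (ncol(pca$loadings) < 2) stop("need loadings for components 1 and 2")
  out <- lapply(categories, function(cat) {
    ids <- calls$cpg[!is.na(calls$category) & calls$category == cat]
    ids <- intersect(ids, rownames(pca$loadings))
    if (length(ids) < min_n) {
      warning("category '", cat, "' has fewer than ", min_n,
              " CpGs; contrast reported as NA")
      return(data.frame(category = cat, n = length(ids),
                        median_diff = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    d <- abs(pca$loadings[ids, 1]) - abs(pca$loadings[ids, 2])
    nz <- d[abs(d) > 1e-15]
    p <- if (length(nz) == 0) 1 else
      suppressWarnings(stats::wilcox.test(nz, exact = FALSE)$p.value)
    data.frame(category = cat, n = length(ids), median_diff = stats::median(d),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
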