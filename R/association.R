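#' Pearson partial correlation with covariate adjustment
#'
#' Correlation between `x` and `y` after removing the least-squares
#' contribution of the covariates `Z` (plus an intercept) from each:
#' \eqn{r} is the Pearson correlation of the two residual vectors,
#' tested with \eqn{t = r\sqrt{(n-2-k)/(1-r^2)}} on \eqn{n-2-k} degrees of
#' freedom.
#'
#' If one variable is exactly explained by the covariates its residual is
#' null and the partial correlation is 0 by orthogonality; this is returned
#' (with a warning) rather than treated as an error.
#'
#' @param x,y numeric subject-level vectors.
#' @param Z optional covariate matrix/data.frame (subjects x k).
#' @return one-row data.frame: `r`, `t`, `df`, `p`, `n`, `k`.
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant x or y")
  }
  k <- 0L
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != n) stop("Z rows must match length of x")
    if (anyNA(Z)) stop("missing values in Z")
    storage.mode(Z) <- "double"
    k <- ncol(Z)
  }
  if (n <= k + 2) stop("need n > k + 2 subjects")
  Zm <- cbind(`(Intercept)` = rep(1, n), Z)
  qz <- qr(Zm)
  if (qz$rank < ncol(Zm)) {
    bad <- colnames(Zm)[qz$pivot[(qz$rank + 1):ncol(Zm)]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  sx <- sqrt(sum(rx^2))
  sy <- sqrt(sum(ry^2))
  tol <- 1e-10 * sqrt(n)
  if (sx < tol * max(1, stats::sd(x)) || sy < tol * max(1, stats::sd(y))) {
    warning("zero residual variance after covariate adjustment; r set to 0")
    return(data.frame(r = 0, t = 0, df = n - 2L - k, p = 1, n = n, k = k))
  }
  r <- sum(rx * ry) / (sx * sy)
  r <- max(-1, min(1, r))
  df <- n - 2L - k
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(r = r, t = t, df = df, p = p, n = n, k = k)
}

residualize <- function(M, Zm) {
  qz <- qr(Zm)
  if (qz$rank < ncol(Zm)) {
    bad <- colnames(Zm)[qz$pivot[(qz$rank + 1):ncol(Zm)]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qz, M)
}

#' Scan partial correlations between CpG change rates and organ paces
#'
#' Computes, for every (CpG, organ) pair, the covariate-adjusted Pearson
#' partial correlation between the subject-level methylation change rate
#' (random-slope BLUP) and the organ's composite pace of aging. Intended
#' for the age-varying CpG set. p-values are raw by default (flagging at
#' `p < alpha`), with an optional Benjamini-Hochberg adjustment.
#'
#' @param slopes subject x CpG matrix of change rates (see [change_rates()]).
#' @param paces subject x organ matrix (see [organ_composite()]).
#' @param covariates subject-level covariate data.frame/matrix aligned by
#'   rownames (see [collapse_covariates()]).
#' @param alpha significance threshold on the (possibly adjusted) p-value.
#' @param adjust `"none"` (raw p, as conventional for this scan) or `"BH"`.
#' @return data.frame with one row per (CpG, organ): `cpg`, `organ`, `r`,
#'   `t`, `df`, `p`, `significant`; per-organ significant counts in
#'   `attr(, "organ_counts")`.
#' @export
cpg_organ_scan <- function(slopes, paces, covariates = NULL, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.matrix(slopes), is.matrix(paces))
  if (!identical(rownames(slopes), rownames(paces))) {
    if (is.null(rownames(slopes)) || is.null(rownames(paces)) ||
        !setequal(rownames(slopes), rownames(paces))) {
      stop("subject mismatch between slope matrix and pace matrix")
    }
    paces <- paces[rownames(slopes), , drop = FALSE]
  }
  n <- nrow(slopes)
  k <- 0L
  Zm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    Zc <- as.matrix(as.data.frame(covariates))
    storage.mode(Zc) <- "double"
    if (!is.null(rownames(Zc)) && setequal(rownames(Zc), rownames(slopes))) {
      Zc <- Zc[rownames(slopes), , drop = FALSE]
    } else if (nrow(Zc) != n) {
      stop("subject mismatch between slope matrix and covariates")
    }
    k <- ncol(Zc)
    Zm <- cbind(Zm, Zc)
  }
  if (n <= k + 2) stop("need n > k + 2 subjects")
  rx <- residualize(slopes, Zm)
  ry <- residualize(paces, Zm)
  rx <- sweep(rx, 2, sqrt(colSums(rx^2)), `/`)
  ry <- sweep(ry, 2, sqrt(colSums(ry^2)), `/`)
  R <- crossprod(rx, ry)  # CpG x organ
  R[!is.finite(R)] <- 0
  R <- pmin(pmax(R, -1), 1)
  df <- n - 2L - k
  Tm <- R * sqrt(df / pmax(1 - R^2, 1e-300))
  P <- 2 * stats::pt(-abs(Tm), df)
  out <- data.frame(
    cpg = rep(rownames(R), times = ncol(R)),
    organ = rep(colnames(R), each = nrow(R)),
    r = as.vector(R), t = as.vector(Tm), df = df, p = as.vector(P),
    stringsAsFactors = FALSE
  )
  pshow <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- pshow < alpha | alpha >= 1
  counts <- tapply(out$significant, out$organ, sum)
  attr(out, "organ_counts") <- counts[colnames(paces)]
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  out
}

#' Associations of a baseline risk factor with CpG change rates
#'
#' Regresses each CpG's subject-level methylation change rate on a baseline
#' risk factor (e.g. BMI or socioeconomic status) with covariate
#' adjustment, flags CpGs significant at `p < alpha`, and contrasts the
#' significant counts between the age-varying and age-associated categories
#' with a two-sided Fisher exact test.
#'
#' @param factor numeric subject-level vector (one baseline value per
#'   subject).
#' @param slopes subject x CpG change-rate matrix.
#' @param covariates subject-level covariates (matrix/data.frame) or NULL.
#' @param categories character vector (or factor) of CpG category labels
#'   aligned with `colnames(slopes)`, or a [classify_cpgs()] result.
#' @param alpha per-CpG significance threshold.
#' @return list: `records` (per-CpG data.frame with `estimate`, `t`, `p`,
#'   `significant`, `category`), `contrast` (the Fisher
#'   [fisher_exact_2x2()] result on category x significance), `table`.
#' @export
riskfactor_scan <- function(factor, slopes, covariates = NULL,
                            categories = NULL, alpha = 0.05) {
  stopifnot(is.matrix(slopes))
  factor <- as.numeric(factor)
  n <- nrow(slopes)
  if (length(factor) != n) stop("factor length must equal number of subjects")
  if (stats::sd(factor) == 0) stop("degenerate input: constant risk factor")
  X <- cbind(`(Intercept)` = 1, factor = factor)
  if (!is.null(covariates)) {
    Zc <- as.matrix(as.data.frame(covariates))
    storage.mode(Zc) <- "double"
    X <- cbind(X, Zc)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient regression design")
  p <- ncol(X)
  coefs <- qr.coef(qx, slopes)
  res <- qr.resid(qx, slopes)
  rss <- colSums(res^2)
  dfree <- n - p
  XtXinv <- chol2inv(qr.R(qx)[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(rss / dfree * XtXinv[2, 2])
  tval <- coefs["factor", ] / se
  pval <- 2 * stats::pt(-abs(tval), dfree)
  records <- data.frame(
    cpg = colnames(slopes), estimate = coefs["factor", ], t = tval,
    p = pval, significant = pval < alpha | alpha >= 1,
    stringsAsFactors = FALSE, row.names = NULL
  )
  contrast <- NULL
  tab <- NULL
  if (!is.null(categories)) {
    if (inherits(categories, "cpg_calls")) {
      categories <- stats::setNames(categories$category, categories$cpg)[colnames(slopes)]
    }
    records$category <- as.character(categories)
    av <- records$category == "age_varying"
    aa <- records$category == "age_associated"
    tab <- matrix(c(sum(av & records$significant, na.rm = TRUE),
                    sum(av & !records$significant, na.rm = TRUE),
                    sum(aa & records$significant, na.rm = TRUE),
                    sum(aa & !records$significant, na.rm = TRUE)),
                  2, 2, byrow = TRUE,
                  dimnames = list(c("age_varying", "age_associated"),
                                  c("significant", "not_significant")))
    contrast <- fisher_exact_2x2(tab)
  }
  list(records = records, contrast = contrast, table = tab)
}
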