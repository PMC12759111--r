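#' Build a longitudinal design for mixed-model fitting
#'
#' Converts a long-format sample sheet (one row per observation) into the
#' design object consumed by [fit_lmm()] and the genome-wide scan. Rows are
#' ordered by subject and age, the fixed-effect design matrix is assembled
#' from centred age plus the adjustment covariates, and per-subject
#' cross-products are precomputed so that thousands of responses can be
#' fitted against the same design cheaply.
#'
#' Age is centred at the cohort mean *baseline* age (each subject's earliest
#' observation) before entering the model. Centring decorrelates random
#' intercepts and slopes and makes the intercept interpretable as the level
#' at the average baseline age; slopes stay in units per year.
#'
#' @param sample_sheet data.frame with one row per observation. Must contain
#'   `subject_col`, `age_col`, `sample_col` and every column named in
#'   `covariates`.
#' @param covariates character vector of adjustment covariate column names
#'   (numeric or factor). Default matches a blood-methylation ageing study:
#'   sex, smoking, drinking and five leukocyte subtype proportions.
#' @param subject_col,age_col,sample_col column names for the subject
#'   identifier, age in years, and sample identifier.
#' @param age_center centring constant in years; defaults to the mean
#'   baseline age of the cohort.
#' @return An object of class `longitudinal_design`: the reordered data, the
#'   fixed-effect matrix `X`, random-effect matrix `Z` (intercept and centred
#'   age), subject index blocks and the centring constant.
#' @examples
#' sheet <- data.frame(
#'   sample_id = paste0("s", 1:6), subject_id = rep(c("a", "b"), each = 3),
#'   age = c(70, 72.5, 75, 74, 76.5, 79), sex = rep(c(0, 1), each = 3)
#' )
#' d <- longitudinal_design(sheet, covariates = "sex")
#' d$age_center
#' @export
longitudinal_design <- function(sample_sheet,
                                covariates = c("sex", "smoking", "drinking",
                                               "cd8t", "cd4t", "nk", "bcell", "mono"),
                                subject_col = "subject_id",
                                age_col = "age",
                                sample_col = "sample_id",
                                age_center = NULL) {
  stopifnot(is.data.frame(sample_sheet))
  needed <- c(subject_col, age_col, sample_col, covariates)
  missing_cols <- setdiff(needed, names(sample_sheet))
  if (length(missing_cols)) {
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- sample_sheet
  if (!all(is.finite(df[[age_col]]))) stop("non-finite ages in sample sheet")
  for (cv in covariates) {
    if (anyNA(df[[cv]])) stop("covariate '", cv, "' contains missing values")
  }
  df <- df[order(df[[subject_col]], df[[age_col]]), , drop = FALSE]
  rownames(df) <- NULL

  subj <- as.character(df[[subject_col]])
  if (is.null(age_center)) {
    baseline <- tapply(df[[age_col]], subj, min)
    age_center <- mean(baseline)
  }
  age_c <- df[[age_col]] - age_center

  mm_data <- cbind(data.frame(age = age_c), df[, covariates, drop = FALSE])
  X <- stats::model.matrix(stats::reformulate(c("age", covariates)), data = mm_data)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("degenerate design: constant or collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Z <- cbind(1, age_c)

  runs <- rle(subj)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)

  structure(list(
    data = df, X = X, Z = Z,
    starts0 = as.integer(starts - 1L), ends0 = as.integer(ends - 1L),
    subjects = runs$values, n = nrow(df), n_subjects = length(runs$values),
    age_center = age_center, sample_ids = as.character(df[[sample_col]]),
    covariates = covariates
  ), class = "longitudinal_design")
}

#' @export
print.longitudinal_design <- function(x, ...) {
  cat("longitudinal design:", x$n, "observations,", x$n_subjects, "subjects\n")
  cat("  age centred at", round(x$age_center, 3), "years;",
      ncol(x$X), "fixed-effect columns\n")
  invisible(x)
}

#' Collapse observation-level covariates to one row per subject
#'
#' Subject-level analyses (partial correlations between methylation change
#' rates and organ paces) adjust for subject-level covariates. Time-varying
#' columns are collapsed: age, smoking and drinking are taken at baseline
#' (earliest observation), leukocyte proportions and any other numeric
#' covariate as the within-subject mean.
#'
#' @param design a [longitudinal_design()].
#' @param baseline_cols covariates taken from the baseline visit.
#' @return data.frame with one row per subject (rownames = subject ids):
#'   baseline `age` plus the collapsed covariates.
#' @export
collapse_covariates <- function(design,
                                baseline_cols = c("sex", "smoking", "drinking")) {
  stopifnot(inherits(design, "longitudinal_design"))
  df <- design$data
  subj <- as.character(df[[1]])  # placeholder, replaced below
  subj <- rep(design$subjects, times = design$ends0 - design$starts0 + 1L)
  first <- design$starts0 + 1L
  out <- data.frame(row.names = design$subjects)
  out$age <- tapply(df$age, subj, min)[design$subjects]
  for (cv in design$covariates) {
    v <- df[[cv]]
    if (cv %in% baseline_cols || !is.numeric(v)) {
      out[[cv]] <- v[first]
    } else {
      out[[cv]] <- as.numeric(tapply(v, subj, mean)[design$subjects])
    }
  }
  out
}
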