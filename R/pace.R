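#' Impute a phenotype panel for pace-of-aging modelling
#'
#' Deterministic completion of a sample-aligned phenotype panel: phenotypes
#' missing in more than `max_missing_fraction` of cells are dropped (with a
#' message); remaining holes are filled by within-subject linear
#' interpolation on age, falling back to the subject mean and finally the
#' cohort mean. The procedure is deliberately deterministic so repeated
#' pipeline runs are reproducible.
#'
#' @param panel data.frame whose rows align with `design$data`; a
#'   `sample_id` column, if present, is used to align and is preserved.
#' @param design a [longitudinal_design()].
#' @param max_missing_fraction drop threshold on the per-phenotype missing
#'   fraction (strictly greater than).
#' @return completed panel (same row order as the design), with dropped
#'   phenotype names in `attr(, "dropped")`.
#' @export
impute_phenotypes <- function(panel, design, max_missing_fraction = 0.2) {
  stopifnot(is.data.frame(panel), inherits(design, "longitudinal_design"))
  if ("sample_id" %in% names(panel)) {
    if (!all(design$sample_ids %in% panel$sample_id)) {
      stop("phenotype panel does not cover the design's sample ids")
    }
    panel <- panel[match(design$sample_ids, panel$sample_id), , drop = FALSE]
    ids <- panel$sample_id
    panel$sample_id <- NULL
  } else {
    if (nrow(panel) != design$n) stop("panel rows do not match the design")
    ids <- design$sample_ids
  }
  rownames(panel) <- NULL

  frac <- vapply(panel, function(v) mean(is.na(v)), numeric(1))
  drop <- names(frac)[frac > max_missing_fraction]
  all_missing <- names(frac)[frac == 1]
  if (length(all_missing)) {
    warning("phenotype(s) entirely missing, dropped: ",
            paste(all_missing, collapse = ", "))
  }
  if (length(setdiff(drop, all_missing))) {
    message("dropped phenotype(s) with > ", max_missing_fraction,
            " missing: ", paste(setdiff(drop, all_missing), collapse = ", "))
  }
  panel <- panel[, setdiff(names(panel), drop), drop = FALSE]

  subj <- rep(design$subjects, times = design$ends0 - design$starts0 + 1L)
  age <- design$data$age
  for (ph in names(panel)) {
    v <- panel[[ph]]
    if (!anyNA(v)) next
    cohort_mean <- mean(v, na.rm = TRUE)
    for (s in unique(subj[is.na(v)])) {
      ix <- which(subj == s)
      obs <- ix[!is.na(v[ix])]
      mis <- ix[is.na(v[ix])]
      if (length(obs) >= 2) {
        v[mis] <- stats::approx(age[obs], v[obs], xout = age[mis],
                                rule = 1)$y
        mis <- ix[is.na(v[ix])]
      }
      if (length(mis) && length(obs) >= 1) {
        v[mis] <- mean(v[obs])
        mis <- ix[is.na(v[ix])]
      }
      if (length(mis)) v[mis] <- cohort_mean
    }
    panel[[ph]] <- v
  }
  out <- cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE), panel)
  attr(out, "dropped") <- drop
  out
}

#' Phenotype-specific pace of aging from random slopes
#'
#' Fits, for each phenotype, a linear mixed model with random intercepts and
#' random slopes on centred age with full covariate adjustment, and returns
#' each subject's random-slope BLUP as the phenotype-specific pace of aging
#' (phenotype units per year, as a deviation from the population trend).
#'
#' @param panel completed phenotype panel (see [impute_phenotypes()]); a
#'   `sample_id` column is used for alignment if present.
#' @param design a [longitudinal_design()].
#' @return subject x phenotype matrix of paces, with non-converged
#'   phenotypes excluded (warning).
#' @export
phenotype_pace <- function(panel, design) {
  stopifnot(is.data.frame(panel), inherits(design, "longitudinal_design"))
  if ("sample_id" %in% names(panel)) {
    panel <- panel[match(design$sample_ids, panel$sample_id), , drop = FALSE]
    panel$sample_id <- NULL
  } else if (nrow(panel) != design$n) {
    stop("panel rows do not match the design")
  }
  if (anyNA(panel)) stop("panel contains missing values; run impute_phenotypes() first")
  paces <- matrix(NA_real_, design$n_subjects, ncol(panel),
                  dimnames = list(design$subjects, names(panel)))
  bad <- character(0)
  for (ph in names(panel)) {
    f <- fit_lmm(design, panel[[ph]], "intercept_slope")
    if (!f$converged) {
      bad <- c(bad, ph)
      next
    }
    paces[, ph] <- f$blups$b1
  }
  if (length(bad)) {
    warning("non-converged phenotype(s) excluded: ", paste(bad, collapse = ", "))
    paces <- paces[, setdiff(colnames(paces), bad), drop = FALSE]
  }
  paces
}

#' Organ-system composite pace of aging
#'
#' Aggregates phenotype-specific paces into one pace per organ system: each
#' phenotype's pace is aligned with ageing by its configured direction
#' \eqn{d_k} and the arithmetic mean is taken across the organ's
#' phenotypes. By default paces are z-scored across subjects before
#' averaging, because phenotypes carry incommensurable units and an
#' unstandardised mean would be dominated by whichever phenotype has the
#' largest numeric scale; set `standardize = FALSE` for the raw aligned
#' mean.
#'
#' @param paces subject x phenotype matrix from [phenotype_pace()].
#' @param config an [organ_config()] table.
#' @param standardize z-score each phenotype's pace across subjects first.
#' @return subject x organ matrix; organs whose phenotypes all dropped out
#'   are `NA` with a warning. Metadata (directions used, standardization) in
#'   attributes.
#' @export
organ_composite <- function(paces, config, standardize = TRUE) {
  config <- organ_config(config)
  stopifnot(is.matrix(paces))
  organs <- unique(config$organ)
  out <- matrix(NA_real_, nrow(paces), length(organs),
                dimnames = list(rownames(paces), organs))
  missing_ph <- setdiff(config$phenotype, colnames(paces))
  if (length(missing_ph)) {
    message("phenotype(s) absent from pace panel: ",
            paste(missing_ph, collapse = ", "))
  }
  for (org in organs) {
    rows <- config[config$organ == org & config$phenotype %in% colnames(paces), ]
    if (nrow(rows) == 0) {
      warning("organ '", org, "' has no surviving phenotypes; composite is NA")
      next
    }
    aligned <- vapply(seq_len(nrow(rows)), function(k) {
      v <- paces[, rows$phenotype[k]]
      if (standardize) {
        s <- stats::sd(v)
        v <- if (s > 0) (v - mean(v)) / s else v * 0
      }
      rows$direction[k] * v
    }, numeric(nrow(paces)))
    out[, org] <- rowMeans(aligned)
  }
  attr(out, "standardize") <- standardize
  attr(out, "directions") <- stats::setNames(config$direction, config$phenotype)
  out
}
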