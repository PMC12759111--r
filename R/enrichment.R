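#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value sums hypergeometric probabilities, over all tables
#' with the observed margins, that do not exceed the observed table's
#' probability (with a small relative slack of 1e-7 to absorb floating-point
#' ties). The reported odds ratio is the sample OR \eqn{ad/bc}; when any
#' cell is zero the Haldane-Anscombe correction (+0.5 to every cell) is
#' applied to the OR and its Wald confidence interval only -- the exact
#' p-value is always computed on the raw counts.
#'
#' @param a,b,c,d cell counts, or a 2x2 matrix as `a`.
#' @param conf_level confidence level for the Wald interval on log OR.
#' @return object of class `enrichment_result`: `table`, `odds_ratio`,
#'   `log2_odds_ratio`, `conf_int`, `p_value`, `haldane` (correction
#'   applied), `empty_margin` flag.
#' @examples
#' fisher_exact_2x2(5, 1, 2, 10)
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             conf_level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2, 2)
  }
  cells <- as.vector(tab)  # a, c, b, d column-major
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("empty table")
  a_ <- tab[1, 1]; b_ <- tab[1, 2]; c_ <- tab[2, 1]; d_ <- tab[2, 2]
  empty_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)

  p <- fisher_p_twosided(a_, b_, c_, d_)

  haldane <- any(tab == 0)
  oc <- if (haldane) c(a_, b_, c_, d_) + 0.5 else c(a_, b_, c_, d_)
  or <- oc[1] * oc[4] / (oc[2] * oc[3])
  se <- sqrt(sum(1 / oc))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * zq * se)

  structure(list(table = tab, odds_ratio = or, log2_odds_ratio = log2(or),
                 conf_int = ci, p_value = p, haldane = haldane,
                 empty_margin = empty_margin, conf_level = conf_level),
            class = "enrichment_result")
}

# Two-sided exact p by enumeration over the hypergeometric support.
fisher_p_twosided <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  n1 <- a + c
  if (m1 == 0 || m2 == 0 || n1 == 0 || b + d == 0) return(1)
  lo <- max(0, n1 - m2)
  hi <- min(n1, m1)
  x <- lo:hi
  probs <- stats::dhyper(x, m1, m2, n1)
  p_obs <- probs[x == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Fisher exact 2x2: OR =", signif(x$odds_ratio, 4),
      sprintf("[%s, %s]", signif(x$conf_int[1], 4), signif(x$conf_int[2], 4)),
      " p =", format(x$p_value, digits = 4), "\n")
  if (x$haldane) cat("  (Haldane-Anscombe correction applied to OR/CI)\n")
  if (x$empty_margin) cat("  (table has an empty margin)\n")
  invisible(x)
}

category_sets <- function(calls) {
  ok <- !is.na(calls$category)
  list(
    age_associated = calls$cpg[ok & calls$category %in% c("age_associated", "both")],
    age_varying = calls$cpg[ok & calls$category %in% c("age_varying", "both")]
  )
}

#' Enrichment of CpG categories in epigenetic-clock CpG sets
#'
#' For each clock list and each CpG category (age-associated and
#' age-varying, each including the overlap), builds the 2x2 table of clock
#' membership against category membership over the analysed universe and
#' applies [fisher_exact_2x2()]. Clock lists are intersected with the
#' universe first, so CpGs absent from the analysed data never enter any
#' cell. p-values are Benjamini-Hochberg adjusted across the clock x
#' category grid; log2 odds ratios and confidence bounds are included for
#' forest-plot style output.
#'
#' @param calls a [classify_cpgs()] result.
#' @param clock_lists named list of CpG id vectors.
#' @param universe analysed CpG ids (defaults to all CpGs in `calls`).
#' @return data.frame: `clock`, `category`, `n_clock` (in-universe clock
#'   size), `a`,`b`,`c`,`d`, `odds_ratio`, `log2_or`, `ci_lo`, `ci_hi`, `p`,
#'   `adj_p`, `empty` flag.
#' @export
clock_enrichment <- function(calls, clock_lists, universe = NULL) {
  stopifnot(inherits(calls, "cpg_calls"), is.list(clock_lists))
  if (is.null(universe)) universe <- calls$cpg
  sets <- lapply(category_sets(calls), intersect, y = universe)
  rows <- list()
  for (cl in names(clock_lists)) {
    in_clock <- intersect(clock_lists[[cl]], universe)
    for (cat in names(sets)) {
      in_cat <- sets[[cat]]
      if (length(in_clock) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          clock = cl, category = cat, n_clock = 0L, a = NA_integer_,
          b = NA_integer_, c = NA_integer_, d = NA_integer_,
          odds_ratio = NA_real_, log2_or = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, p = NA_real_, empty = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      a <- length(intersect(in_clock, in_cat))
      b <- length(in_clock) - a
      c_ <- length(in_cat) - a
      d <- length(universe) - a - b - c_
      fr <- fisher_exact_2x2(a, b, c_, d)
      rows[[length(rows) + 1]] <- data.frame(
        clock = cl, category = cat, n_clock = length(in_clock),
        a = a, b = b, c = c_, d = d,
        odds_ratio = fr$odds_ratio, log2_or = fr$log2_odds_ratio,
        ci_lo = fr$conf_int[1], ci_hi = fr$conf_int[2], p = fr$p_value,
        empty = fr$empty_margin, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, "BH")
  out
}

#' DHS enrichment contrast between age-varying and age-associated CpGs
#'
#' Tests whether age-varying CpGs fall in DNase I hypersensitive (open
#' chromatin) regions more often than age-associated CpGs, via the 2x2
#' table of exclusive category (`age_varying` vs `age_associated`) against
#' DHS status. An odds ratio above 1 means age-varying CpGs are more often
#' in DHS regions.
#'
#' @param calls a [classify_cpgs()] result.
#' @param dhs named 0/1 (or logical) vector of DHS flags covering every
#'   called CpG.
#' @return an `enrichment_result` (see [fisher_exact_2x2()]).
#' @export
dhs_enrichment <- function(calls, dhs) {
  stopifnot(inherits(calls, "cpg_calls"))
  ok <- !is.na(calls$category) & calls$category %in% c("age_varying", "age_associated")
  ids <- calls$cpg[ok]
  if (!all(ids %in% names(dhs))) {
    stop("DHS flag missing for ", sum(!(ids %in% names(dhs))), " CpG(s)")
  }
  flag <- as.logical(as.numeric(dhs[ids]))
  av <- calls$category[ok] == "age_varying"
  fisher_exact_2x2(sum(av & flag), sum(av & !flag),
                   sum(!av & flag), sum(!av & !flag))
}

genomic_features <- function() {
  c("First Exon", "5'UTR", "Exon Boundary", "TSS1500",
    "3'UTR", "Body", "IGR", "TSS200")
}

#' Genomic-feature distribution of CpG categories
#'
#' Tabulates counts and within-category proportions of the age-associated
#' and age-varying CpGs over the eight genomic feature classes, and tests
#' category-by-feature independence with a Pearson chi-square test.
#'
#' @param calls a [classify_cpgs()] result.
#' @param features named character vector mapping CpG id to one of the
#'   eight feature labels.
#' @return list: `counts` (2 x 8), `proportions` (rows sum to 1),
#'   `statistic`, `p_value`.
#' @export
feature_distribution <- function(calls, features) {
  stopifnot(inherits(calls, "cpg_calls"))
  lv <- genomic_features()
  unknown <- setdiff(unique(features), lv)
  if (length(unknown)) {
    stop("unknown genomic feature label(s): ", paste(unknown, collapse = ", "))
  }
  ok <- !is.na(calls$category) & calls$category %in% c("age_varying", "age_associated")
  ids <- calls$cpg[ok]
  if (!all(ids %in% names(features))) {
    stop("feature annotation missing for some called CpGs")
  }
  f <- factor(features[ids], levels = lv)
  g <- factor(calls$category[ok], levels = c("age_associated", "age_varying"))
  counts <- table(category = g, feature = f)
  props <- counts / rowSums(counts)
  ct <- suppressWarnings(stats::chisq.test(counts[, colSums(counts) > 0]))
  list(counts = counts, proportions = props,
       statistic = unname(ct$statistic), p_value = ct$p.value)
}
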