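#' Default organ-system configuration
#'
#' Eight organ systems, each with a small panel of macro-phenotypes, a
#' direction of change with ageing (`+1` increases, `-1` decreases) and, for
#' the simulator, a coupling `rho` between the phenotype's per-subject slope
#' and the latent organ ageing rate. This is a compact synthetic stand-in
#' for a full clinical phenotype inventory: real analyses supply their own
#' table via [organ_config()].
#'
#' @param rho default coupling of each phenotype to its organ's latent rate.
#' @return data.frame with columns `organ`, `phenotype`, `direction`, `rho`,
#'   `scale` (unit scale used by the simulator).
#' @export
default_organ_config <- function(rho = 0.6) {
  cfg <- data.frame(
    organ = rep(c("brain", "cardiovascular", "immune", "kidney",
                  "liver", "metabolic", "musculoskeletal", "physical"),
                each = 2),
    phenotype = c("reaction_time", "cognitive_score",
                  "systolic_bp", "pulse_pressure",
                  "crp", "lymphocyte_ratio",
                  "creatinine", "egfr",
                  "alt", "albumin",
                  "fasting_glucose", "hba1c",
                  "grip_strength", "bmi",
                  "gait_speed", "adl_score"),
    direction = c(+1, -1, +1, +1, +1, -1, +1, -1,
                  +1, -1, +1, +1, -1, -1, -1, +1),
    stringsAsFactors = FALSE
  )
  cfg$rho <- rho
  cfg$scale <- rep(c(1, 10, 0.5, 100), 4)
  cfg
}

#' Validate an organ-system configuration table
#'
#' @param x data.frame with columns `organ`, `phenotype`, `direction` and
#'   optionally `rho` (simulator coupling) and `scale`.
#' @return the validated data.frame, class `organ_config`.
#' @export
organ_config <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("organ", "phenotype", "direction")
  if (!all(need %in% names(x))) {
    stop("organ config needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(x$phenotype)) {
    stop("each phenotype must appear in exactly one organ system; duplicated: ",
         paste(unique(x$phenotype[duplicated(x$phenotype)]), collapse = ", "))
  }
  if (!all(x$direction %in% c(-1, 1))) stop("directions must be +1 or -1")
  if (!is.null(x$rho) && any(abs(x$rho) > 1)) stop("|rho| must be <= 1")
  class(x) <- c("organ_config", "data.frame")
  x
}

#' Configuration for the synthetic longitudinal cohort
#'
#' Collects the generative parameters of the simulated cohort: a
#' three-wave longitudinal design of older adults with per-CpG Gaussian
#' random-intercept/random-slope trajectories on the beta scale, adjustment
#' covariates including a five-part leukocyte-proportion simplex, and organ
#' phenotypes whose per-subject slopes are coupled to latent organ ageing
#' rates.
#'
#' CpG sites fall into four classes: `null` (no age signal),
#' `age_associated` (a common mean slope `beta_age_mean` per year),
#' `age_varying` (between-subject slope SD `slope_sd`, zero mean slope) and
#' `both`. Defaults mirror a three-wave, five-year study of 70-81 year-olds;
#' effect sizes are calibration choices exposed here, not estimates of any
#' particular cohort.
#'
#' @param n_subjects number of subjects.
#' @param n_cpgs number of CpG sites.
#' @param wave_offsets follow-up offsets in years, starting at 0, strictly
#'   increasing.
#' @param baseline_age_range uniform range of baseline ages (years).
#' @param female_fraction proportion of female subjects.
#' @param class_fractions named proportions over
#'   `c(null, age_associated, age_varying, both)`; must sum to 1.
#' @param beta_age_mean fixed age effect (beta-units/year) for the
#'   age-associated classes.
#' @param slope_sd between-subject slope SD (beta-units/year, sigma_b1) for
#'   the age-varying classes.
#' @param intercept_sd between-subject intercept SD (beta-units, sigma_b0).
#' @param residual_sd residual SD (beta-units, sigma_e).
#' @param intercept_slope_corr correlation of random intercept and slope.
#' @param cell_type_concentration Dirichlet parameters for the leukocyte
#'   simplex. The five lymphoid/myeloid subtypes (cd8t, cd4t, nk, bcell,
#'   mono) are emitted as covariates; the dominant `gran` (granulocyte)
#'   fraction closes the simplex and stays implicit, so the emitted
#'   proportions are not collinear with the model intercept.
#' @param cell_effects fixed-effect coefficients of the 5 cell proportions
#'   on methylation (small non-zero defaults so adjustment is exercised).
#' @param organ_cfg organ/phenotype table (see [default_organ_config()]).
#' @param phenotype_slope_sd between-subject SD of phenotype slopes, in
#'   z-units/year before per-phenotype rescaling.
#' @param phenotype_residual_sd residual SD of phenotypes (z-units).
#' @param cpg_organ_rho coupling between planted age-varying CpG slopes and
#'   latent organ rates (0 disables; used for power studies of the
#'   slope-pace association).
#' @param n_coupled_cpgs number of age-varying CpGs coupled to organ rates
#'   (assigned to organs round-robin).
#' @param missing_rate cell-wise missingness injected into the phenotype
#'   panel (0 = complete).
#' @param scale `"beta"` simulates on the beta scale with clamping to
#'   \eqn{[0,1]}; `"m"` leaves trajectories unclamped on an M-value-like
#'   scale.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 135,
                          n_cpgs = 2000,
                          wave_offsets = c(0, 2.5, 5),
                          baseline_age_range = c(70, 81),
                          female_fraction = 0.615,
                          class_fractions = c(null = 0.70, age_associated = 0.15,
                                              age_varying = 0.10, both = 0.05),
                          beta_age_mean = 0.002,
                          slope_sd = 0.003,
                          intercept_sd = 0.02,
                          residual_sd = 0.005,
                          intercept_slope_corr = 0,
                          cell_type_concentration = c(cd8t = 4, cd4t = 8, nk = 2,
                                                      bcell = 2, mono = 3,
                                                      gran = 30),
                          cell_effects = c(cd8t = 0.02, cd4t = -0.015, nk = 0.01,
                                           bcell = -0.01, mono = 0.015),
                          organ_cfg = default_organ_config(),
                          phenotype_slope_sd = 0.3,
                          phenotype_residual_sd = 0.5,
                          cpg_organ_rho = 0,
                          n_coupled_cpgs = 0,
                          missing_rate = 0,
                          scale = c("beta", "m"),
                          seed = 1L) {
  scale <- match.arg(scale)
  classes <- c("null", "age_associated", "age_varying", "both")
  if (!setequal(names(class_fractions), classes)) {
    stop("class_fractions must be named over: ", paste(classes, collapse = ", "))
  }
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class fractions must sum to 1 (got ", sum(class_fractions), ")")
  }
  if (any(class_fractions < 0)) stop("class fractions must be non-negative")
  if (wave_offsets[1] != 0 || is.unsorted(wave_offsets, strictly = TRUE)) {
    stop("wave_offsets must start at 0 and be strictly increasing")
  }
  if (any(c(slope_sd, intercept_sd, residual_sd, phenotype_slope_sd,
            phenotype_residual_sd) < 0)) {
    stop("standard deviations must be >= 0")
  }
  if (abs(intercept_slope_corr) > 1) stop("|intercept_slope_corr| must be <= 1")
  if (slope_sd > 0 &&
      class_fractions[["age_varying"]] + class_fractions[["both"]] == 0) {
    stop("configuration error: slope_sd > 0 but no class carries a random slope")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  organ_cfg <- organ_config(organ_cfg)
  structure(list(
    n_subjects = as.integer(n_subjects), n_cpgs = as.integer(n_cpgs),
    wave_offsets = wave_offsets, baseline_age_range = baseline_age_range,
    female_fraction = female_fraction, class_fractions = class_fractions,
    beta_age_mean = beta_age_mean, slope_sd = slope_sd,
    intercept_sd = intercept_sd, residual_sd = residual_sd,
    intercept_slope_corr = intercept_slope_corr,
    cell_type_concentration = cell_type_concentration,
    cell_effects = cell_effects, organ_cfg = organ_cfg,
    phenotype_slope_sd = phenotype_slope_sd,
    phenotype_residual_sd = phenotype_residual_sd,
    cpg_organ_rho = cpg_organ_rho, n_coupled_cpgs = as.integer(n_coupled_cpgs),
    missing_rate = missing_rate, scale = scale, seed = as.integer(seed)
  ), class = "cohort_config")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Simulate a longitudinal methylation cohort with ground truth
#'
#' Generates a sample sheet, a CpG x sample methylation matrix, a phenotype
#' panel and truth tables under the generative model
#' \deqn{m_{ijt} = \beta_{0j} + \beta_{age,j} a_{it} + \sum_c \gamma_{cj}
#'   x_{cit} + b_{0ij} + b_{1ij} a_{it} + \epsilon_{ijt}}
#' with \eqn{a_{it}} age centred at the cohort mean baseline age,
#' \eqn{(b_0, b_1)} bivariate normal and Gaussian residuals; beta-scale
#' values are clamped to \eqn{[0,1]} and the clamped fraction reported.
#' Each organ phenotype's per-subject slope is built from a latent
#' per-organ ageing rate with coupling `rho`, so that the direction-aligned
#' true slope correlates `rho` with the latent rate.
#'
#' @param config a [cohort_config()].
#' @return list of class `methyl_cohort`: `sample_sheet` (one row per
#'   observation), `meth` (CpG x sample matrix), `phenotypes` (data.frame,
#'   rows aligned with the sample sheet, first column `sample_id`), `truth`
#'   (list: `cpg_class`, `true_subject_slopes` subject x CpG,
#'   `true_fixed_effects`, `true_organ_rate` subject x organ,
#'   `true_phenotype_slopes` subject x phenotype, `cpg_coupling`),
#'   `clamp_fraction`, and the `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 20, n_cpgs = 10, seed = 7))
#' dim(coh$meth)
#' table(coh$truth$cpg_class)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ns <- config$n_subjects
  nw <- length(config$wave_offsets)
  n <- ns * nw
  ncpg <- config$n_cpgs

  subject_id <- sprintf("sub%04d", seq_len(ns))
  baseline <- stats::runif(ns, config$baseline_age_range[1], config$baseline_age_range[2])
  sheet <- data.frame(
    sample_id = paste0(rep(subject_id, each = nw), "_w", rep(seq_len(nw), ns)),
    subject_id = rep(subject_id, each = nw),
    wave = rep(seq_len(nw), ns),
    age = rep(baseline, each = nw) + rep(config$wave_offsets, ns),
    sex = rep(stats::rbinom(ns, 1, config$female_fraction), each = nw),
    smoking = rep(stats::rbinom(ns, 1, 0.30), each = nw),
    drinking = rep(stats::rbinom(ns, 1, 0.25), each = nw),
    stringsAsFactors = FALSE
  )
  # 6-part leukocyte simplex; the dominant granulocyte fraction is left
  # implicit so the 5 retained proportions are not collinear with the
  # intercept
  cells <- rdirichlet(n, config$cell_type_concentration)
  keep_cells <- setdiff(colnames(cells), "gran")[1:5]
  sheet <- cbind(sheet, as.data.frame(cells[, keep_cells, drop = FALSE]))

  age_c <- sheet$age - mean(baseline)
  sub_ix <- rep(seq_len(ns), each = nw)

  # CpG classes and fixed effects
  counts <- floor(config$class_fractions * ncpg)
  rem <- ncpg - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  cpg_class <- rep(names(counts), counts)
  cpg_id <- sprintf("cg%07d", seq_len(ncpg))
  names(cpg_class) <- cpg_id
  beta0 <- stats::runif(ncpg, 0.2, 0.8)
  beta_age <- ifelse(cpg_class %in% c("age_associated", "both"),
                     config$beta_age_mean, 0)
  has_slope <- cpg_class %in% c("age_varying", "both")

  # latent organ rates and phenotype slopes
  ocfg <- config$organ_cfg
  organs <- unique(ocfg$organ)
  U <- matrix(stats::rnorm(ns * length(organs)), ns, length(organs),
              dimnames = list(subject_id, organs))

  # random effects per CpG: intercept b0 always; slope b1 for varying classes
  r <- config$intercept_slope_corr
  b0m <- matrix(stats::rnorm(ns * ncpg, 0, config$intercept_sd), ns, ncpg)
  e1 <- matrix(stats::rnorm(ns * ncpg), ns, ncpg)
  b1m <- matrix(0, ns, ncpg, dimnames = list(subject_id, cpg_id))
  if (any(has_slope) && config$slope_sd > 0) {
    z0 <- if (config$intercept_sd > 0) b0m / config$intercept_sd else
      matrix(stats::rnorm(ns * ncpg), ns, ncpg)
    raw <- r * z0 + sqrt(1 - r^2) * e1
    b1m[, has_slope] <- config$slope_sd * raw[, has_slope]
  }
  cpg_coupling <- NULL
  if (config$n_coupled_cpgs > 0 && config$cpg_organ_rho != 0) {
    idx <- which(has_slope)
    idx <- idx[seq_len(min(length(idx), config$n_coupled_cpgs))]
    org_for <- organs[(seq_along(idx) - 1) %% length(organs) + 1]
    rho_c <- config$cpg_organ_rho
    for (j in seq_along(idx)) {
      b1m[, idx[j]] <- config$slope_sd *
        (rho_c * U[, org_for[j]] + sqrt(1 - rho_c^2) * stats::rnorm(ns))
    }
    cpg_coupling <- data.frame(cpg = cpg_id[idx], organ = org_for,
                               rho = rho_c, stringsAsFactors = FALSE)
  }

  # assemble methylation: obs x cpg then transpose
  covar_cols <- c("cd8t", "cd4t", "nk", "bcell", "mono")
  gamma_fix <- as.matrix(sheet[, covar_cols]) %*% config$cell_effects[covar_cols]
  mu <- outer(drop(gamma_fix), rep(1, ncpg)) +
    rep(1, n) %o% beta0 +
    age_c %o% beta_age +
    b0m[sub_ix, , drop = FALSE] +
    b1m[sub_ix, , drop = FALSE] * age_c
  eps <- matrix(stats::rnorm(n * ncpg, 0, config$residual_sd), n, ncpg)
  meth <- mu + eps
  clamp_fraction <- 0
  if (config$scale == "beta") {
    clamped <- meth < 0 | meth > 1
    clamp_fraction <- mean(clamped)
    meth[meth < 0] <- 0
    meth[meth > 1] <- 1
  }
  meth <- t(meth)
  dimnames(meth) <- list(cpg_id, sheet$sample_id)

  # phenotypes: per-subject slope coupled to the organ's latent rate;
  # direction-aligned slope correlates rho with the rate
  tau <- config$phenotype_slope_sd
  pheno <- data.frame(sample_id = sheet$sample_id, stringsAsFactors = FALSE)
  true_s <- matrix(NA_real_, ns, nrow(ocfg),
                   dimnames = list(subject_id, ocfg$phenotype))
  for (k in seq_len(nrow(ocfg))) {
    rho <- if (is.null(ocfg$rho)) 0.6 else ocfg$rho[k]
    scl <- if (is.null(ocfg$scale)) 1 else ocfg$scale[k]
    d_k <- ocfg$direction[k]
    aligned <- tau * (rho * U[, ocfg$organ[k]] + sqrt(1 - rho^2) * stats::rnorm(ns))
    s_k <- d_k * aligned                      # phenotype-scale slope, z-units/yr
    true_s[, k] <- s_k * scl
    b0p <- stats::rnorm(ns, 0, 1)
    mean_slope <- d_k * 0.1                   # population trend in direction d_k
    vals <- (b0p[sub_ix] + (mean_slope + s_k[sub_ix]) * age_c +
               stats::rnorm(n, 0, config$phenotype_residual_sd)) * scl
    pheno[[ocfg$phenotype[k]]] <- vals
  }
  if (config$missing_rate > 0) {
    pheno <- inject_missing(pheno, config$missing_rate,
                            seed = config$seed + 1L, id_cols = "sample_id")
  }

  structure(list(
    sample_sheet = sheet, meth = meth, phenotypes = pheno,
    truth = list(
      cpg_class = cpg_class,
      true_subject_slopes = b1m,
      true_fixed_effects = data.frame(cpg = cpg_id, beta0 = beta0,
                                      beta_age = beta_age,
                                      stringsAsFactors = FALSE),
      true_organ_rate = U,
      true_phenotype_slopes = true_s,
      cpg_coupling = cpg_coupling
    ),
    clamp_fraction = clamp_fraction,
    age_center = mean(baseline),
    config = config
  ), class = "methyl_cohort")
}

#' @export
print.methyl_cohort <- function(x, ...) {
  cat("synthetic longitudinal cohort:", x$config$n_subjects, "subjects x",
      length(x$config$wave_offsets), "waves;", nrow(x$meth), "CpGs\n")
  cat("  clamped fraction:", signif(x$clamp_fraction, 3), "\n")
  invisible(x)
}

#' Inject missing values into a phenotype panel
#'
#' Masks each data cell independently with probability `missing_rate`,
#' reproducibly by seed. Identifier columns are never masked.
#'
#' @param panel data.frame.
#' @param missing_rate probability in `[0, 1)` of masking a cell.
#' @param seed integer seed for the mask.
#' @param id_cols columns to leave untouched.
#' @return the panel with `NA` holes.
#' @export
inject_missing <- function(panel, missing_rate, seed = 1L,
                           id_cols = "sample_id") {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (missing_rate == 0) return(panel)
  cols <- setdiff(names(panel), id_cols)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (cl in cols) {
    mask <- stats::runif(nrow(panel)) < missing_rate
    panel[[cl]][mask] <- NA
  }
  panel
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic CpG annotation
#'
#' Random gene, genomic-feature and DNase-hypersensitivity annotation for a
#' set of CpG ids, for fixtures and pipeline smoke runs. Features are drawn
#' from the eight standard array feature classes; a configurable fraction of
#' CpGs fall in DHS regions.
#'
#' @param cpg_ids character vector of CpG identifiers.
#' @param n_genes size of the synthetic gene pool.
#' @param dhs_fraction marginal probability of the DHS flag.
#' @param seed integer seed.
#' @return data.frame with columns `cpg`, `gene`, `feature`, `dhs`.
#' @export
simulate_annotation <- function(cpg_ids, n_genes = 400, dhs_fraction = 0.25,
                                seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  features <- c("First Exon", "5'UTR", "Exon Boundary", "TSS1500",
                "3'UTR", "Body", "IGR", "TSS200")
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  data.frame(
    cpg = cpg_ids,
    gene = sample(genes, length(cpg_ids), replace = TRUE),
    feature = sample(features, length(cpg_ids), replace = TRUE,
                     prob = c(.05, .08, .02, .15, .05, .35, .2, .1)),
    dhs = stats::rbinom(length(cpg_ids), 1, dhs_fraction),
    stringsAsFactors = FALSE
  )
}

#' Synthetic epigenetic-clock CpG lists
#'
#' Draws fixture clock CpG sets from a universe of analysed CpGs, sized like
#' the five commonly used clocks' intersections with a single-array dataset
#' (scaled down to the universe at hand). These are synthetic stand-ins, not
#' the published clock CpG sets.
#'
#' @param universe CpG ids to draw from.
#' @param sizes named vector of list sizes; trimmed to the universe size.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
simulate_clock_lists <- function(universe,
                                 sizes = c(hannum = 64, grimage = 327,
                                           zhang = 508, phenoage = 510,
                                           dunedinpace = 169),
                                 seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(as.list(pmin(sizes, length(universe))),
         function(k) sample(universe, k))
}

#' Synthetic gene sets and ontology for enrichment fixtures
#'
#' Builds named gene sets over a gene pool for each of GO/KEGG/Reactome-like
#' sources, plus a random is_a/part_of DAG over the GO-like terms so Wang
#' semantic similarity can be exercised.
#'
#' @param genes gene pool.
#' @param n_sets sets per source.
#' @param set_size range of set sizes.
#' @param seed integer seed.
#' @return list with `gene_sets` (named list source -> named list of gene
#'   vectors) and `ontology_edges` (data.frame child/parent/relation for the
#'   GO-like terms).
#' @export
simulate_gene_sets <- function(genes, n_sets = 30, set_size = c(5, 40),
                               seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mk <- function(prefix) {
    sets <- lapply(seq_len(n_sets), function(i) {
      sample(genes, sample(seq(set_size[1], set_size[2]), 1))
    })
    names(sets) <- sprintf("%s%04d", prefix, seq_len(n_sets))
    sets
  }
  gene_sets <- list(GO = mk("GO:"), KEGG = mk("hsa"), Reactome = mk("R-HSA-"))
  go_terms <- names(gene_sets$GO)
  # random DAG: each term gets a parent among earlier terms
  edges <- data.frame(child = character(0), parent = character(0),
                      relation = character(0), stringsAsFactors = FALSE)
  for (i in seq(2, length(go_terms))) {
    parent <- sample(go_terms[seq_len(i - 1)], 1)
    edges <- rbind(edges, data.frame(
      child = go_terms[i], parent = parent,
      relation = sample(c("is_a", "part_of"), 1, prob = c(.8, .2)),
      stringsAsFactors = FALSE))
  }
  list(gene_sets = gene_sets, ontology_edges = edges)
}
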