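#' Write a table with a commented metadata header
#'
#' All stage outputs are tab-separated UTF-8 text with '.' decimals, 'NA'
#' for missing values, and a commented header recording the tool version,
#' creation time, seed and any decisions in force. Matrices are written
#' with their row identifiers as a first column named by `id_col`.
#'
#' @param x data.frame or matrix.
#' @param path output path.
#' @param meta named list of metadata values.
#' @param id_col name of the identifier column used when `x` is a matrix.
#' @export
write_table_meta <- function(x, path, meta = list(), id_col = "id") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_col
    x <- df
  }
  header <- c(
    paste0("# methylpace: ", as.character(utils::packageVersion("methylpace"))),
    paste0("# created: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    vapply(names(meta), function(k) {
      paste0("# ", k, ": ", paste(meta[[k]], collapse = ",", sep = ""))
    }, character(1))
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a table written by [write_table_meta()]
#'
#' @param path file path.
#' @param ... passed to [utils::read.delim()].
#' @return data.frame with the parsed metadata in `attr(, "meta")`.
#' @export
read_table_meta <- function(path, ...) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, n = 50, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos > 0) {
      meta[[substr(kv, 1, pos - 1)]] <- trimws(substr(kv, pos + 1, nchar(kv)))
    }
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, ...)
  attr(df, "meta") <- meta
  df
}

#' Read a methylation matrix from TSV
#'
#' Expects CpGs in rows and samples in columns (standard array convention),
#' with the first column holding CpG ids. If the first header token is
#' `sample_id` the matrix is recognised as transposed and flipped, with a
#' message.
#'
#' @param path TSV path.
#' @return CpG x sample numeric matrix.
#' @export
read_methylation <- function(path) {
  df <- read_table_meta(path)
  first <- names(df)[1]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (tolower(first) %in% c("sample_id", "sample")) {
    message("methylation matrix recognised as sample x CpG; transposing")
    m <- t(m)
  }
  m
}

#' Read a sample sheet TSV
#' @param path TSV path.
#' @return data.frame (one row per observation).
#' @export
read_sample_sheet <- function(path) read_table_meta(path)

#' Read a phenotype panel TSV (rows = samples, first column `sample_id`)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) read_table_meta(path)

#' Read an organ configuration TSV (columns organ, phenotype, direction)
#' @param path TSV path.
#' @return validated [organ_config()] table.
#' @export
read_organ_config <- function(path) organ_config(read_table_meta(path))

#' Read a CpG annotation TSV (columns cpg, gene, feature, dhs)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  ann <- read_table_meta(path)
  need <- c("cpg", "gene", "feature", "dhs")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  ann
}

#' Read a clock CpG list (one CpG id per line; '#' comments allowed)
#' @param path text file path.
#' @return character vector of CpG ids.
#' @export
read_clock_list <- function(path) {
  if (!file.exists(path)) stop("clock list not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x[!grepl("^#", x)])
  x[nzchar(x)]
}

#' Read ontology edges TSV (columns child, parent, relation)
#' @param path TSV path.
#' @return an [ontology_graph()].
#' @export
read_ontology <- function(path) ontology_graph(read_table_meta(path))

#' Write all synthetic cohort components to a directory
#'
#' Emits `sample_sheet.tsv`, `methylation.tsv`, `phenotypes.tsv` and the
#' truth tables (`truth_cpg_class.tsv`, `truth_subject_slopes.tsv`,
#' `truth_organ_rate.tsv`, `truth_fixed_effects.tsv`), plus the organ
#' configuration and a YAML copy of the generator configuration.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "methyl_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = cohort$config$seed,
               n_subjects = cohort$config$n_subjects,
               clamp_fraction = signif(cohort$clamp_fraction, 6))
  paths <- c(
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    organ_config = file.path(dir, "organ_config.tsv"),
    truth_cpg_class = file.path(dir, "truth_cpg_class.tsv"),
    truth_subject_slopes = file.path(dir, "truth_subject_slopes.tsv"),
    truth_organ_rate = file.path(dir, "truth_organ_rate.tsv"),
    truth_fixed_effects = file.path(dir, "truth_fixed_effects.tsv"),
    config = file.path(dir, "cohort_config.yaml")
  )
  write_table_meta(cohort$sample_sheet, paths["sample_sheet"], meta)
  write_table_meta(cohort$meth, paths["methylation"], meta, id_col = "cpg")
  write_table_meta(cohort$phenotypes, paths["phenotypes"], meta)
  write_table_meta(as.data.frame(cohort$config$organ_cfg),
                   paths["organ_config"], meta)
  write_table_meta(data.frame(cpg = names(cohort$truth$cpg_class),
                              class = unname(cohort$truth$cpg_class)),
                   paths["truth_cpg_class"], meta)
  write_table_meta(cohort$truth$true_subject_slopes,
                   paths["truth_subject_slopes"], meta, id_col = "subject_id")
  write_table_meta(cohort$truth$true_organ_rate, paths["truth_organ_rate"],
                   meta, id_col = "subject_id")
  write_table_meta(cohort$truth$true_fixed_effects,
                   paths["truth_fixed_effects"], meta)
  cfg <- cohort$config
  cfg$organ_cfg <- NULL
  yaml::write_yaml(unclass(cfg), paths["config"])
  invisible(paths)
}
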