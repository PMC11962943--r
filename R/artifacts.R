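#' Write / read a labelled numeric matrix as TSV
#'
#' Row labels go in the first column (`row`), column labels in the header.
#' Values are written at full precision so round trips are exact.
#'
#' @param M A numeric matrix with dimnames.
#' @param path Output path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(M, path) {
  df <- format_full_precision(as_tibble(M, rownames = "row"))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  ng_assert(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df[-1])
  rownames(M) <- as.character(df[[1]])
  M
}

#' Serialize a pattern model to a directory
#'
#' Writes the signature matrix (patterns x phenotypes) as TSV, the
#' vocabulary (with categories) as TSV, and the hyperparameters (including
#' the seed) as a YAML sidecar, so a model directory is self-describing and
#' sufficient to map external cohorts.
#'
#' @param model A `pattern_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pattern_model <- function(model, dir) {
  ng_assert(inherits(model, "pattern_model"), "expected a pattern_model")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ng_assert(!is.null(rownames(model$signatures)), "signatures need row names")
  write_matrix_tsv(model$signatures, file.path(dir, "signatures.tsv"))
  readr::write_tsv(as_tibble(model$vocabulary),
                   file.path(dir, "vocabulary.tsv"))
  if (!is.null(model$categories)) {
    readr::write_tsv(model$categories, file.path(dir, "pattern_categories.tsv"))
  }
  yaml::write_yaml(model$hyperparameters,
                   file.path(dir, "hyperparameters.yaml"))
  invisible(dir)
}

#' @rdname write_pattern_model
#' @export
read_pattern_model <- function(dir) {
  sig_path <- file.path(dir, "signatures.tsv")
  ng_assert(file.exists(sig_path), paste0("not a model directory: ", dir))
  S <- read_matrix_tsv(sig_path)
  vocab_df <- readr::read_tsv(file.path(dir, "vocabulary.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  vocab <- phenotype_vocabulary(vocab_df$phenotype, vocab_df$category)
  hp <- yaml::read_yaml(file.path(dir, "hyperparameters.yaml"))
  cat_path <- file.path(dir, "pattern_categories.tsv")
  categories <- if (file.exists(cat_path)) {
    readr::read_tsv(cat_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  structure(list(labels = NULL, signatures = S, vocabulary = vocab,
                 patient_id = NULL, hyperparameters = hp,
                 categories = categories),
            class = "pattern_model")
}

#' Write all artifacts of a fitted model
#'
#' Writes the pattern model, per-patient histogram and proportion matrices,
#' the kernel matrix, the population edge list, subgroup assignments, the
#' characteristic-pattern report, survival summaries, and a manifest with
#' the configuration and seed.
#'
#' @param fit A [softwl_fit()] object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fit_artifacts <- function(fit, dir) {
  ng_assert(inherits(fit, "softwl_fit"), "expected a softwl_fit")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pattern_model(fit$model, file.path(dir, "model"))
  readr::write_tsv(fit$histograms, file.path(dir, "histograms.tsv"))
  readr::write_tsv(fit$proportions, file.path(dir, "proportions.tsv"))
  write_matrix_tsv(fit$kernel, file.path(dir, "kernel.tsv"))
  readr::write_tsv(fit$population$edges,
                   file.path(dir, "population_edges.tsv"))
  readr::write_tsv(fit$subgroups, file.path(dir, "subgroups.tsv"))
  if (!is.null(fit$characteristic)) {
    readr::write_tsv(fit$characteristic,
                     file.path(dir, "characteristic_patterns.tsv"))
  }
  if (!is.null(fit$survival)) {
    if (!is.null(fit$survival$cox)) {
      readr::write_tsv(fit$survival$cox, file.path(dir, "cox_subgroups.tsv"))
    }
    readr::write_tsv(fit$survival$km, file.path(dir, "km_curves.tsv"))
  }
  manifest <- list(config = unclass(fit$config),
                   seed = fit$config$random_seed,
                   n_patients = length(fit$population$patient_id),
                   n_patterns = nrow(fit$model$signatures),
                   n_subgroups = max(fit$subgroups$subgroup),
                   version = as.character(utils::packageVersion("nichegraph")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
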