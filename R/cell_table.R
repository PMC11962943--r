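#' Read a per-cell table
#'
#' Reads a CSV/TSV file with one row per segmented cell and validates it into
#' the canonical cell-table layout: `patient_id`, `image_id`, `x`, `y`
#' (centroid coordinates in micrometers) and `phenotype`, plus any
#' antigen-expression columns carried along unchanged. Column names in the
#' file are mapped through `schema`.
#'
#' @param path Path to a delimited text file. The delimiter is inferred from
#'   the extension (`.tsv`/`.txt` read as tab, otherwise comma).
#' @param schema Named character vector mapping canonical names
#'   (`patient_id`, `image_id`, `x`, `y`, `phenotype`) to the column names
#'   used in the file.
#' @param vocabulary Optional [phenotype_vocabulary()]. When supplied, any
#'   phenotype outside the vocabulary is an error unless
#'   `allow_new_phenotypes = TRUE`.
#' @param allow_new_phenotypes If `TRUE` (default when no vocabulary is
#'   given), unseen phenotypes are accepted and the vocabulary is built from
#'   the data.
#'
#' @return A validated cell-table tibble.
#' @seealso [filter_patients()], [write_cell_table()]
#' @export
read_cell_table <- function(path,
                            schema = c(patient_id = "patient_id",
                                       image_id = "image_id",
                                       x = "x", y = "y",
                                       phenotype = "phenotype"),
                            vocabulary = NULL,
                            allow_new_phenotypes = is.null(vocabulary)) {
  ng_assert(file.exists(path), paste0("file not found: ", path))
  schema <- utils::modifyList(
    as.list(c(patient_id = "patient_id", image_id = "image_id",
              x = "x", y = "y", phenotype = "phenotype")),
    as.list(schema))
  raw <- read_delim_auto(path)
  missing <- setdiff(unlist(schema), names(raw))
  ng_assert(length(missing) == 0,
            paste0("missing column(s) in ", path, ": ",
                   paste(missing, collapse = ", ")))
  cells <- tibble(
    patient_id = as.character(raw[[schema$patient_id]]),
    image_id   = as.character(raw[[schema$image_id]]),
    x          = raw[[schema$x]],
    y          = raw[[schema$y]],
    phenotype  = as.character(raw[[schema$phenotype]])
  )
  extra <- setdiff(names(raw), unlist(schema))
  if (length(extra)) cells <- bind_cols(cells, raw[extra])
  validate_cell_table(cells, vocabulary = vocabulary,
                      allow_new_phenotypes = allow_new_phenotypes)
}

# base R parsing (strtod) is used so that doubles written at 17 significant
# digits round-trip bit-exactly
read_delim_auto <- function(path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  as_tibble(utils::read.delim(path, sep = delim, check.names = FALSE,
                              stringsAsFactors = FALSE))
}

#' Validate a cell table
#'
#' Checks the invariants every downstream stage relies on: required columns
#' present, coordinates numeric and finite, phenotypes within the vocabulary.
#' Offending rows are named in the error message.
#'
#' @inheritParams read_cell_table
#' @param cells A data frame with columns `patient_id`, `image_id`, `x`, `y`,
#'   `phenotype`.
#' @return The cell table as a tibble (invisibly unchanged apart from type
#'   coercion of id columns).
#' @export
validate_cell_table <- function(cells, vocabulary = NULL,
                                allow_new_phenotypes = is.null(vocabulary)) {
  need <- c("patient_id", "image_id", "x", "y", "phenotype")
  missing <- setdiff(need, names(cells))
  ng_assert(length(missing) == 0,
            paste0("cell table lacks column(s): ", paste(missing, collapse = ", ")))
  cells <- as_tibble(cells)
  cells$patient_id <- as.character(cells$patient_id)
  cells$image_id <- as.character(cells$image_id)
  cells$phenotype <- as.character(cells$phenotype)
  for (col in c("x", "y")) {
    v <- cells[[col]]
    ng_assert(is.numeric(v), paste0("column `", col, "` is not numeric"))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      ng_stop(paste0("non-finite coordinate in column `", col, "` at row(s) ",
                     paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (!is.null(vocabulary) && !allow_new_phenotypes) {
    vocabulary <- as_phenotype_vocabulary(vocabulary)
    unknown <- setdiff(unique(cells$phenotype), vocabulary$phenotype)
    ng_assert(length(unknown) == 0,
              paste0("phenotype(s) outside the vocabulary: ",
                     paste(unknown, collapse = ", ")))
  }
  cells
}

#' Write a cell table to disk
#'
#' Coordinates are written at full precision so that a written table re-read
#' with [read_cell_table()] reproduces the original exactly.
#'
#' @param cells A cell table.
#' @param path Output path; `.tsv` writes tab-separated, anything else comma.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(format_full_precision(cells), path, delim = delim)
  invisible(path)
}

# doubles rendered with 17 significant digits round-trip exactly
format_full_precision <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- sprintf("%.17g", df[[col]])
    }
  }
  df
}

#' Exclude patients with too few cells
#'
#' Patients whose total cell count, summed over all their images, falls below
#' `min_cells` are removed. Sparse cores give unstable neighborhood
#' statistics, so cohort studies routinely exclude them before any modelling.
#' Counting is per patient, not per image: a patient contributing several
#' small cores is kept when the pooled count reaches the threshold.
#'
#' @param cells A cell table.
#' @param min_cells Minimum total cell count (strictly fewer is excluded);
#'   default 500.
#' @return The filtered cell table. Excluded patient ids are attached as
#'   attribute `"excluded"` and reported via a message.
#' @export
filter_patients <- function(cells, min_cells = 500) {
  ng_assert(is.numeric(min_cells) && min_cells >= 1, "min_cells must be >= 1")
  cells <- validate_cell_table(cells)
  counts <- cells |> count(.data$patient_id, name = "n_cells")
  drop <- counts$patient_id[counts$n_cells < min_cells]
  if (length(drop)) {
    inform(paste0("filter_patients: excluding ", length(drop),
                  " patient(s) with fewer than ", min_cells, " cells: ",
                  paste(head(drop, 10), collapse = ", "),
                  if (length(drop) > 10) ", ..." else ""))
  }
  out <- cells |> filter(!.data$patient_id %in% drop)
  attr(out, "excluded") <- drop
  out
}

#' Read a per-patient clinical table
#'
#' @param path Path to a delimited file keyed by `patient_id`.
#' @param schema Named character vector mapping canonical names
#'   (`patient_id`, `survival_time`, `event`) to file columns. Any further
#'   columns (subtype, grade, stage, age, response, ...) are carried along.
#' @return A validated clinical tibble.
#' @export
read_clinical_table <- function(path,
                                schema = c(patient_id = "patient_id",
                                           survival_time = "survival_time",
                                           event = "event")) {
  ng_assert(file.exists(path), paste0("file not found: ", path))
  schema <- utils::modifyList(
    as.list(c(patient_id = "patient_id", survival_time = "survival_time",
              event = "event")),
    as.list(schema))
  raw <- read_delim_auto(path)
  missing <- setdiff(unlist(schema), names(raw))
  ng_assert(length(missing) == 0,
            paste0("missing column(s) in ", path, ": ",
                   paste(missing, collapse = ", ")))
  clin <- tibble(
    patient_id    = as.character(raw[[schema$patient_id]]),
    survival_time = raw[[schema$survival_time]],
    event         = raw[[schema$event]]
  )
  extra <- setdiff(names(raw), unlist(schema))
  if (length(extra)) clin <- bind_cols(clin, raw[extra])
  validate_clinical_table(clin)
}

#' Validate a clinical table
#'
#' @param clinical A data frame with `patient_id`, `survival_time` (months,
#'   nonnegative) and `event` (0 = censored, 1 = event).
#' @return The clinical table as a tibble.
#' @export
validate_clinical_table <- function(clinical) {
  need <- c("patient_id", "survival_time", "event")
  missing <- setdiff(need, names(clinical))
  ng_assert(length(missing) == 0,
            paste0("clinical table lacks column(s): ",
                   paste(missing, collapse = ", ")))
  clinical <- as_tibble(clinical)
  clinical$patient_id <- as.character(clinical$patient_id)
  ng_assert(!anyDuplicated(clinical$patient_id),
            "clinical table has duplicated patient ids")
  ng_assert(is.numeric(clinical$survival_time) &&
              all(clinical$survival_time >= 0, na.rm = TRUE),
            "survival_time must be numeric and nonnegative")
  ng_assert(all(clinical$event %in% c(0, 1, NA)),
            "event must be 0 (censored) or 1 (event)")
  clinical
}
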