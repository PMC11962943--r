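#' Phenotype vocabulary
#'
#' An ordered set of cell-phenotype labels, each assigned to one of the three
#' broad cell-type categories used throughout spatial tumor-microenvironment
#' analysis: `tumor`, `immune`, or `stromal`. The vocabulary order is fixed
#' when a model is fitted; all one-hot encodings, embedding columns, and
#' signature columns follow it.
#'
#' @param phenotype Character vector of distinct, non-empty phenotype labels.
#' @param category Character vector (recycled if length 1) giving the category
#'   of each phenotype; one of `"tumor"`, `"immune"`, `"stromal"`, or `NA`
#'   when no categorisation is available.
#'
#' @return A tibble of class `phenotype_vocabulary` with columns `phenotype`
#'   and `category`, rows in vocabulary order.
#' @examples
#' phenotype_vocabulary(c("epithelial", "t_cell", "fibroblast"),
#'                      c("tumor", "immune", "stromal"))
#' @export
phenotype_vocabulary <- function(phenotype, category = NA_character_) {
  phenotype <- as.character(phenotype)
  ng_assert(length(phenotype) >= 1, "vocabulary must contain at least one phenotype")
  ng_assert(!anyNA(phenotype) && all(nzchar(phenotype)),
            "phenotype labels must be non-empty")
  ng_assert(!anyDuplicated(phenotype), "phenotype labels must be unique")
  category <- as.character(category)
  if (length(category) == 1L) category <- rep(category, length(phenotype))
  ng_assert(length(category) == length(phenotype),
            "`category` must have one entry per phenotype")
  bad <- !is.na(category) & !category %in% c("tumor", "immune", "stromal")
  ng_assert(!any(bad), "categories must be one of tumor, immune, stromal (or NA)")
  out <- tibble(phenotype = phenotype, category = category)
  class(out) <- c("phenotype_vocabulary", class(out))
  out
}

#' Build a vocabulary from observed cell phenotypes
#'
#' Phenotypes are taken in sorted order so that the vocabulary (and hence all
#' downstream encodings) is independent of row order. Categories are left `NA`
#' unless a lookup is supplied.
#'
#' @param cells A cell table (see [read_cell_table()]).
#' @param categories Optional named character vector mapping phenotype to
#'   category.
#' @return A [phenotype_vocabulary()].
#' @export
vocabulary_from_cells <- function(cells, categories = NULL) {
  ng_assert("phenotype" %in% names(cells), "cell table lacks a phenotype column")
  ph <- sort(unique(as.character(cells$phenotype)))
  cat <- if (is.null(categories)) NA_character_ else unname(categories[ph])
  phenotype_vocabulary(ph, cat)
}

is_phenotype_vocabulary <- function(x) inherits(x, "phenotype_vocabulary")

as_phenotype_vocabulary <- function(x) {
  if (is_phenotype_vocabulary(x)) return(x)
  if (is.data.frame(x) && all(c("phenotype", "category") %in% names(x))) {
    return(phenotype_vocabulary(x$phenotype, x$category))
  }
  if (is.character(x)) return(phenotype_vocabulary(x))
  ng_stop("cannot interpret object as a phenotype vocabulary")
}
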