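#' Fit the full bi-level model on a discovery cohort
#'
#' Runs the complete discovery pipeline: patient filtering, Gaussian
#' cellular graphs, depth-`h` subtree embeddings, PhenoGraph-style pattern
#' discovery, pattern histograms and the cosine kernel, the k-NN/IoU
#' population graph with Louvain subgroups, characteristic-pattern
#' identification, pattern categorisation, and (when clinical data are
#' supplied) subgroup survival analysis.
#'
#' @param cells Cohort cell table.
#' @param clinical Optional clinical tibble; enables the survival stage.
#' @param vocabulary Optional [phenotype_vocabulary()]; default built from
#'   the data (sorted phenotypes, no categories).
#' @param config An [run_config()]; defaults everywhere.
#' @return An object of class `softwl_fit` with components `model`
#'   (`pattern_model`), `assignments`, `histograms`, `proportions`, `kernel`,
#'   `population` (`population_graph` with subgroups), `subgroups` (tibble),
#'   `characteristic`, `categories`, `survival` (list with `logrank`, `cox`,
#'   `km`) or `NULL`, plus `vocabulary`, `config`, and (if expression columns
#'   were present) `centroids`.
#' @export
softwl_fit <- function(cells, clinical = NULL, vocabulary = NULL,
                       config = run_config()) {
  ng_assert(inherits(config, "ng_config"), "config must come from run_config()")
  cells <- validate_cell_table(cells)
  vocabulary <- if (is.null(vocabulary)) vocabulary_from_cells(cells)
                else as_phenotype_vocabulary(vocabulary)
  cells <- filter_patients(cells, min_cells = config$min_cells)
  ng_assert(nrow(cells) > 0, "no patients left after filtering")

  embeddings <- compute_subtree_embeddings(
    cells, vocabulary = vocabulary, alpha = config$alpha, h = config$h,
    sparsify_epsilon = config$sparsify_epsilon)
  model <- cluster_subtrees(embeddings, k_pheno = config$k_pheno,
                            seed = config$random_seed,
                            vocabulary = vocabulary)
  assignments <- pattern_assignments(model, embeddings)
  histograms <- pattern_histograms(assignments, C = nrow(model$signatures))
  proportions <- normalize_histograms(histograms)
  K <- kernel_matrix(histograms)

  n <- nrow(K)
  k_star <- min(config$k_star, n - 1)
  if (k_star < config$k_star) {
    warn(paste0("k_star reduced to ", k_star, " for a cohort of ", n,
                " patients"))
  }
  population <- build_population_graph(K, k_star = k_star) |>
    detect_communities(seed = config$random_seed)
  subgroups <- tidy(population)

  characteristic <- NULL
  if (max(subgroups$subgroup) >= 2) {
    characteristic <- characteristic_patterns(
      proportions, subgroups, hl_fraction = config$hl_fraction)
  }
  categories <- model$categories

  centroids <- NULL
  antigens <- antigen_columns(cells)
  if (length(antigens)) {
    centroids <- fit_phenotype_centroids(cells, antigens)
  }

  surv <- NULL
  if (!is.null(clinical)) {
    clinical <- validate_clinical_table(clinical)
    grouping <- tibble(patient_id = subgroups$patient_id,
                       group = subgroups$subgroup)
    surv <- list(
      logrank = if (max(subgroups$subgroup) >= 2)
        multivariate_logrank(clinical, grouping) else NULL,
      cox = if (max(subgroups$subgroup) >= 2)
        cox_subgroup_hr(clinical, subgroups) else NULL,
      km = km_estimate(clinical, grouping))
  }

  structure(list(model = model, assignments = assignments,
                 histograms = histograms, proportions = proportions,
                 kernel = K, population = population, subgroups = subgroups,
                 characteristic = characteristic, categories = categories,
                 centroids = centroids, survival = surv,
                 vocabulary = vocabulary, config = config),
            class = "softwl_fit")
}

antigen_columns <- function(cells) {
  cand <- setdiff(names(cells),
                  c("patient_id", "image_id", "x", "y", "phenotype",
                    "niche", "archetype", "phenotype_original"))
  cand[vapply(cells[cand], is.numeric, logical(1))]
}

#' @export
print.softwl_fit <- function(x, ...) {
  cat("<softwl_fit>\n")
  cat("  patients:  ", length(x$population$patient_id), "\n")
  cat("  phenotypes:", nrow(x$vocabulary), "\n")
  cat("  patterns:  ", nrow(x$model$signatures), "\n")
  cat("  subgroups: ", max(x$subgroups$subgroup),
      sprintf(" (modularity %.3f)\n", x$population$modularity))
  if (!is.null(x$survival$logrank)) {
    cat(sprintf("  log-rank:   chi2 = %.3f, df = %d, p = %.3g\n",
                x$survival$logrank$statistic, x$survival$logrank$df,
                x$survival$logrank$p.value))
  }
  invisible(x)
}

#' @export
tidy.softwl_fit <- function(x, ...) {
  left_join(x$subgroups, x$proportions, by = "patient_id")
}

#' @export
glance.softwl_fit <- function(x, ...) {
  tibble(n_patients = length(x$population$patient_id),
         n_phenotypes = nrow(x$vocabulary),
         n_patterns = nrow(x$model$signatures),
         n_subgroups = max(x$subgroups$subgroup),
         modularity = x$population$modularity,
         logrank_p = if (!is.null(x$survival$logrank))
           x$survival$logrank$p.value else NA_real_)
}

#' @export
print.pattern_model <- function(x, ...) {
  cat("<pattern_model>", nrow(x$signatures), "patterns over",
      nrow(x$vocabulary), "phenotypes;",
      length(x$labels), "subtrees; modularity",
      signif(x$hyperparameters$modularity, 4), "\n")
  invisible(x)
}

#' Signatures of a pattern model as a tidy tibble
#'
#' @param x A `pattern_model`.
#' @param ... Unused.
#' @return A long tibble with `pattern`, `phenotype`, `signature`, and
#'   pattern `size`.
#' @export
tidy.pattern_model <- function(x, ...) {
  S <- x$signatures
  size <- tabulate(x$labels, nbins = nrow(S))
  as_tibble(S, rownames = "pattern") |>
    tidyr::pivot_longer(-"pattern", names_to = "phenotype",
                        values_to = "signature") |>
    left_join(tibble(pattern = rownames(S), size = size), by = "pattern")
}

#' @export
glance.pattern_model <- function(x, ...) {
  tibble(n_patterns = nrow(x$signatures),
         n_subtrees = length(x$labels),
         n_phenotypes = nrow(x$vocabulary),
         k_pheno = x$hyperparameters$k_pheno,
         modularity = x$hyperparameters$modularity)
}

#' Project an external cohort onto a fitted model
#'
#' Maps an external cohort at the three levels of the fitted model: cells to
#' discovery phenotypes (only needed, and only possible, when expression
#' values over shared antigens are available), subtrees to discovery
#' patterns (nearest signature), and patients to discovery subgroups
#' (similarity-weighted k-NN vote). Without expression data the external
#' phenotypes must already lie in the fitted vocabulary.
#'
#' @param fit A [softwl_fit()] object.
#' @param cells External cohort cell table.
#' @param map_phenotypes If `TRUE`, remap cell phenotypes through the fitted
#'   expression centroids; default `FALSE`.
#' @param clinical Optional clinical table for survival analysis of the
#'   mapped subgroups.
#' @return An object of class `softwl_map` with `cells` (possibly
#'   re-phenotyped), `assignments`, `histograms`, `proportions`,
#'   `subgroups`, and optional `survival`.
#' @export
softwl_map <- function(fit, cells, map_phenotypes = FALSE, clinical = NULL) {
  ng_assert(inherits(fit, "softwl_fit"), "expected a softwl_fit")
  cells <- validate_cell_table(cells)
  ng_assert(nrow(cells) > 0, "external cell table is empty")
  if (map_phenotypes) {
    ng_assert(!is.null(fit$centroids),
              "fit carries no expression centroids; cannot map phenotypes")
    cells <- map_cell_phenotypes(cells, fit$centroids)
  } else {
    unknown <- setdiff(unique(cells$phenotype), fit$vocabulary$phenotype)
    ng_assert(length(unknown) == 0,
              paste0("external phenotype(s) outside the fitted vocabulary ",
                     "(supply expression data and map_phenotypes = TRUE): ",
                     paste(unknown, collapse = ", ")))
  }
  cells <- filter_patients(cells, min_cells = fit$config$min_cells)
  ng_assert(nrow(cells) > 0, "no external patients left after filtering")
  embeddings <- compute_subtree_embeddings(
    cells, vocabulary = fit$vocabulary, alpha = fit$config$alpha,
    h = fit$config$h, sparsify_epsilon = fit$config$sparsify_epsilon)
  mapped <- map_subtrees_to_patterns(embeddings, fit$model)
  proportions <- normalize_histograms(mapped$histograms)
  subgroups <- map_patients_to_subgroups(
    mapped$histograms, fit$histograms, fit$subgroups,
    knn_map = fit$config$knn_map)
  surv <- NULL
  if (!is.null(clinical) && length(unique(subgroups$subgroup)) >= 2) {
    clinical <- validate_clinical_table(clinical)
    grouping <- tibble(patient_id = subgroups$patient_id,
                       group = subgroups$subgroup)
    surv <- list(logrank = multivariate_logrank(clinical, grouping),
                 cox = cox_subgroup_hr(clinical, subgroups),
                 km = km_estimate(clinical, grouping))
  }
  structure(list(cells = cells, assignments = mapped$assignments,
                 histograms = mapped$histograms, proportions = proportions,
                 subgroups = subgroups, survival = surv),
            class = "softwl_map")
}

#' @export
print.softwl_map <- function(x, ...) {
  cat("<softwl_map>", nrow(x$subgroups), "external patients mapped to",
      length(unique(x$subgroups$subgroup)), "subgroup(s)\n")
  invisible(x)
}

#' Comparator pipelines with alternative patient representations
#'
#' Keeps the downstream machinery of [softwl_fit()] (cosine kernel,
#' k-NN/IoU population graph, Louvain subgroups, survival analysis) but
#' swaps the patient representation for one of the comparator schemes:
#' `cell_abundance` (phenotype histogram), `pairwise_proximity` (mean
#' Gaussian proximity per phenotype pair), `category_abundance` (histogram
#' over the four niche categories; requires a fitted `model`),
#' `wl_accumulated` / `wl_last` (classic WL subtree-kernel features on the
#' binarized graphs), or `external` (any per-patient embedding supplied via
#' `profiles`, e.g. from a published graph-embedding method).
#'
#' @param cells Cohort cell table (ignored for `scheme = "external"`).
#' @param clinical Optional clinical tibble.
#' @param scheme One of `"cell_abundance"`, `"pairwise_proximity"`,
#'   `"category_abundance"`, `"wl_accumulated"`, `"wl_last"`, `"external"`.
#' @param config An [run_config()].
#' @param model A fitted `softwl_fit` (needed for `category_abundance`).
#' @param profiles Per-patient feature tibble (`patient_id` + numeric
#'   columns) for `scheme = "external"`.
#' @param wl_threshold Edge-weight cutoff for graph binarization in the WL
#'   schemes; default 0.01.
#' @return An object of class `comparator_fit` with `profiles`, `kernel`,
#'   `population`, `subgroups`, optional `survival`, and the `scheme`.
#' @export
comparator_fit <- function(cells, clinical = NULL,
                           scheme = c("cell_abundance", "pairwise_proximity",
                                      "category_abundance", "wl_accumulated",
                                      "wl_last", "external"),
                           config = run_config(), model = NULL,
                           profiles = NULL, wl_threshold = 0.01) {
  scheme <- tryCatch(match.arg(scheme), error = function(e) {
    ng_stop(paste0("unknown scheme `", scheme[1], "`; valid schemes: ",
                   "cell_abundance, pairwise_proximity, category_abundance, ",
                   "wl_accumulated, wl_last, external"))
  })
  if (scheme != "external") {
    cells <- filter_patients(validate_cell_table(cells),
                             min_cells = config$min_cells)
    ng_assert(nrow(cells) > 0, "no patients left after filtering")
  }
  profiles <- switch(
    scheme,
    cell_abundance = cell_abundance_profiles(cells),
    pairwise_proximity = pairwise_proximity_profiles(cells,
                                                     alpha = config$alpha),
    category_abundance = {
      ng_assert(inherits(model, "softwl_fit"),
                "category_abundance needs a fitted softwl_fit as `model`")
      category_abundance_profiles(model$assignments, model$categories)
    },
    wl_accumulated = ,
    wl_last = {
      graphs <- purrr::map(split(cells, cells$patient_id), function(pc) {
        suppressMessages(binarize_graph(
          build_cellular_graph(pc, alpha = config$alpha,
                               sparsify_epsilon = config$sparsify_epsilon),
          threshold = wl_threshold))
      })
      wl <- wl_color_refinement(graphs, h = config$h)
      wl_features(wl, mode = sub("^wl_", "", scheme),
                  patient_id = names(graphs))
    },
    external = {
      ng_assert(is.data.frame(profiles) && "patient_id" %in% names(profiles),
                "external scheme needs a profiles tibble with patient_id")
      as_tibble(profiles)
    })
  K <- kernel_matrix(profiles)
  k_star <- min(config$k_star, nrow(K) - 1)
  population <- build_population_graph(K, k_star = k_star) |>
    detect_communities(seed = config$random_seed)
  subgroups <- tidy(population)
  surv <- NULL
  if (!is.null(clinical) && max(subgroups$subgroup) >= 2) {
    clinical <- validate_clinical_table(clinical)
    grouping <- tibble(patient_id = subgroups$patient_id,
                       group = subgroups$subgroup)
    surv <- list(logrank = multivariate_logrank(clinical, grouping),
                 cox = cox_subgroup_hr(clinical, subgroups),
                 km = km_estimate(clinical, grouping))
  }
  structure(list(profiles = profiles, kernel = K, population = population,
                 subgroups = subgroups, survival = surv, scheme = scheme,
                 config = config),
            class = "comparator_fit")
}

#' @export
print.comparator_fit <- function(x, ...) {
  cat("<comparator_fit>", x$scheme, "|",
      length(x$population$patient_id), "patients |",
      max(x$subgroups$subgroup), "subgroups\n")
  invisible(x)
}
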