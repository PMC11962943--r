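#' Per-phenotype expression centroids over shared antigens
#'
#' When an external cohort was stained with a different antibody panel, its
#' cells are aligned to the discovery phenotypes through the antigens both
#' panels share: each discovery phenotype is summarised by the mean
#' expression of its cells restricted to the shared antigens.
#'
#' @param cells Discovery cell table carrying one numeric column per antigen.
#' @param shared_antigens Character vector of antigen column names present in
#'   both cohorts.
#' @return An object of class `phenotype_centroids`: a tibble with
#'   `phenotype` and one column per shared antigen, rows in vocabulary
#'   (sorted phenotype) order.
#' @export
fit_phenotype_centroids <- function(cells, shared_antigens) {
  cells <- validate_cell_table(cells)
  missing <- setdiff(shared_antigens, names(cells))
  ng_assert(length(missing) == 0,
            paste0("antigen column(s) absent: ", paste(missing, collapse = ", ")))
  for (a in shared_antigens) {
    ng_assert(is.numeric(cells[[a]]) && !anyNA(cells[[a]]),
              paste0("antigen `", a, "` must be numeric and complete"))
  }
  out <- cells |>
    group_by(phenotype = .data$phenotype) |>
    summarise(across(all_of(shared_antigens), mean), .groups = "drop") |>
    arrange(.data$phenotype)
  # discovery-cohort per-antigen location/scale, kept for optional z-scaling
  # at mapping time
  structure(out, class = c("phenotype_centroids", class(out)),
            antigens = shared_antigens,
            antigen_mean = vapply(cells[shared_antigens], mean, numeric(1)),
            antigen_sd = vapply(cells[shared_antigens], stats::sd, numeric(1)))
}

#' Map external cells to the nearest discovery phenotype
#'
#' Each external cell is assigned the discovery phenotype whose expression
#' centroid (over the shared antigens) is closest in Euclidean distance.
#' Ties break to the lower phenotype index and are reported.
#'
#' @param cells External cell table with the shared antigen columns.
#' @param centroids A [fit_phenotype_centroids()] result.
#' @param z_scale If `TRUE`, both the centroids and the external expression
#'   are standardised per antigen using the discovery cohort's mean and sd
#'   before computing distances. Default `FALSE` (raw expression).
#' @return `cells` with its `phenotype` column replaced by the mapped
#'   phenotype (the original kept as `phenotype_original`).
#' @export
map_cell_phenotypes <- function(cells, centroids, z_scale = FALSE) {
  ng_assert(inherits(centroids, "phenotype_centroids"),
            "expected phenotype_centroids")
  antigens <- attr(centroids, "antigens")
  cells <- validate_cell_table(cells)
  missing <- setdiff(antigens, names(cells))
  ng_assert(length(missing) == 0,
            paste0("external table lacks shared antigen(s): ",
                   paste(missing, collapse = ", ")))
  X <- as.matrix(cells[antigens])
  Cm <- as.matrix(centroids[antigens])
  if (z_scale) {
    mu <- attr(centroids, "antigen_mean")
    sd <- pmax(attr(centroids, "antigen_sd"), 1e-12)
    X <- sweep(sweep(X, 2, mu), 2, sd, "/")
    Cm <- sweep(sweep(Cm, 2, mu), 2, sd, "/")
  }
  D2 <- outer(rowSums(X^2), rowSums(Cm^2), "+") - 2 * tcrossprod(X, Cm)
  best <- max.col(-D2, ties.method = "first")
  n_ties <- sum(apply(D2, 1, function(r) sum(abs(r - min(r)) < 1e-12)) > 1)
  if (n_ties > 0) {
    inform(paste0("map_cell_phenotypes: ", n_ties,
                  " cell(s) equidistant to several centroids; ",
                  "assigned the lower-index phenotype"))
  }
  cells$phenotype_original <- cells$phenotype
  cells$phenotype <- centroids$phenotype[best]
  cells
}

#' Map subtrees of an external cohort onto discovery patterns
#'
#' Each external subtree embedding is assigned the discovery pattern with the
#' nearest signature (Euclidean distance, ties to the lower pattern index),
#' and per-patient pattern histograms are rebuilt from the mapped labels.
#'
#' @param embeddings External [compute_subtree_embeddings()] tibble; its
#'   embedding columns must match the model's vocabulary.
#' @param model A fitted `pattern_model`.
#' @return A list with `assignments` (the embeddings tibble plus a `pattern`
#'   column) and `histograms` (a [pattern_histograms()] tibble over the
#'   model's patterns).
#' @export
map_subtrees_to_patterns <- function(embeddings, model) {
  ng_assert(inherits(model, "pattern_model"), "expected a pattern_model")
  E <- embedding_matrix(embeddings)
  S <- model$signatures
  ng_assert(ncol(E) == ncol(S) && all(colnames(E) == colnames(S)),
            "embedding columns do not match the model signatures")
  D2 <- outer(rowSums(E^2), rowSums(S^2), "+") - 2 * tcrossprod(E, S)
  labels <- max.col(-D2, ties.method = "first")
  assignments <- mutate(as_tibble(embeddings), pattern = labels)
  list(assignments = assignments,
       histograms = pattern_histograms(assignments, C = nrow(S)))
}

#' Assign external patients to discovery subgroups
#'
#' Computes the Soft-WL kernel similarity of each external patient against
#' every discovery patient, keeps the `knn_map` most similar discovery
#' patients (ties by index), and assigns the subgroup with the largest sum of
#' similarities among those neighbors. A tied vote falls back to the
#' subgroup of the single most similar neighbor.
#'
#' @param external_profiles Pattern-histogram tibble of the external cohort
#'   (over the discovery model's patterns).
#' @param discovery_profiles Pattern-histogram tibble of the discovery
#'   cohort.
#' @param discovery_subgroups A data frame with `patient_id` and `subgroup`
#'   for the discovery patients.
#' @param knn_map Neighbors in the vote; default 3.
#' @return A tibble with `patient_id`, assigned `subgroup`, and the id and
#'   similarity of the nearest discovery neighbor.
#' @export
map_patients_to_subgroups <- function(external_profiles, discovery_profiles,
                                      discovery_subgroups, knn_map = 3) {
  knn_map <- as.integer(knn_map)
  disc_ids <- discovery_profiles$patient_id
  ng_assert(length(disc_ids) >= knn_map,
            "discovery cohort smaller than knn_map")
  sub <- discovery_subgroups$subgroup[match(disc_ids,
                                            discovery_subgroups$patient_id)]
  ng_assert(!anyNA(sub), "every discovery patient needs a subgroup")
  cols <- setdiff(names(discovery_profiles), "patient_id")
  ng_assert(identical(cols, setdiff(names(external_profiles), "patient_id")),
            "profile columns differ between cohorts")
  Me <- as.matrix(external_profiles[cols])
  Md <- as.matrix(discovery_profiles[cols])
  ng_assert(all(rowSums(Me) > 0), "external patient with all-zero histogram")
  Sim <- tcrossprod(Me / sqrt(rowSums(Me^2)), Md / sqrt(rowSums(Md^2)))
  purrr::map_dfr(seq_len(nrow(Me)), function(i) {
    ord <- order(-Sim[i, ], seq_along(disc_ids))[seq_len(knn_map)]
    votes <- tapply(Sim[i, ord], sub[ord], sum)
    top <- names(votes)[votes == max(votes)]
    win <- if (length(top) == 1L) top else as.character(sub[ord[1]])
    tibble(patient_id = external_profiles$patient_id[i],
           subgroup = utils::type.convert(win, as.is = TRUE),
           nearest_id = disc_ids[ord[1]],
           nearest_similarity = Sim[i, ord[1]])
  })
}
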