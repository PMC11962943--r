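#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with its default. Defaults follow
#' the values commonly used for imaging-mass-cytometry tissue microarrays:
#'
#' * `alpha` — decay rate of the Gaussian edge kernel (1/μm²). At the default
#'   0.01, cells closer than 3 μm have edge weights above 0.9 and cells
#'   farther than 22 μm have weights below 0.01.
#' * `h` — subtree depth / number of graph-convolution sweeps.
#' * `tau` — influence threshold on entries of `A^h` used to delineate the
#'   (reported, not modelled) cellular neighborhood of each subtree root.
#' * `k_pheno` — neighbors in the PhenoGraph-style k-NN graph used to cluster
#'   subtree embeddings into patterns.
#' * `k_star` — neighbors used when rewiring the patient-level population
#'   graph to Jaccard (intersection-over-union) weights.
#' * `min_cells` — patients with fewer total cells are excluded.
#' * `positivity_threshold` — pattern proportion at or above which a patient
#'   counts as pattern-positive for survival stratification.
#' * `hl_fraction` — a pattern is characteristic of a subgroup when its
#'   Hodges-Lehmann statistic strictly exceeds this fraction of the subgroup
#'   maximum.
#' * `knn_map` — neighbors in the similarity-weighted vote assigning external
#'   patients to discovery subgroups.
#' * `sparsify_epsilon` — optional edge-weight cutoff when building cellular
#'   graphs; 0 keeps the exact dense complete graph.
#'
#' @param alpha Gaussian decay rate, > 0. Default 0.01.
#' @param h Subtree depth, integer >= 1. Default 2.
#' @param tau Neighborhood influence threshold, > 0. Default 0.01.
#' @param k_pheno k for subtree clustering, >= 1. Default 100.
#' @param k_star k for the population graph, >= 1. Default 30.
#' @param min_cells Minimum cells per patient, >= 1. Default 500.
#' @param positivity_threshold Proportion threshold in (0,1). Default 0.01.
#' @param hl_fraction Fraction of the subgroup maximum in (0,1]. Default 0.5.
#' @param knn_map Neighbors for cross-cohort subgroup mapping. Default 3.
#' @param sparsify_epsilon Edge-weight cutoff, >= 0 (0 = exact). Default 0.
#' @param random_seed Integer seed recorded in all outputs. Default 1.
#' @return A list of class `ng_config`.
#' @export
run_config <- function(alpha = 0.01, h = 2, tau = 0.01,
                       k_pheno = 100, k_star = 30, min_cells = 500,
                       positivity_threshold = 0.01, hl_fraction = 0.5,
                       knn_map = 3, sparsify_epsilon = 0, random_seed = 1) {
  cfg <- list(alpha = alpha, h = as.integer(h), tau = tau,
              k_pheno = as.integer(k_pheno), k_star = as.integer(k_star),
              min_cells = min_cells,
              positivity_threshold = positivity_threshold,
              hl_fraction = hl_fraction, knn_map = as.integer(knn_map),
              sparsify_epsilon = sparsify_epsilon,
              random_seed = as.integer(random_seed))
  ng_assert(cfg$alpha > 0, "alpha must be > 0")
  ng_assert(cfg$h >= 1, "h must be an integer >= 1")
  ng_assert(cfg$tau > 0, "tau must be > 0")
  ng_assert(cfg$k_pheno >= 1, "k_pheno must be >= 1")
  ng_assert(cfg$k_star >= 1, "k_star must be >= 1")
  ng_assert(cfg$min_cells >= 1, "min_cells must be >= 1")
  ng_assert(cfg$positivity_threshold > 0 && cfg$positivity_threshold < 1,
            "positivity_threshold must be in (0,1)")
  ng_assert(cfg$hl_fraction > 0 && cfg$hl_fraction <= 1,
            "hl_fraction must be in (0,1]")
  ng_assert(cfg$knn_map >= 1, "knn_map must be >= 1")
  ng_assert(cfg$sparsify_epsilon >= 0, "sparsify_epsilon must be >= 0")
  structure(cfg, class = "ng_config")
}

#' @export
print.ng_config <- function(x, ...) {
  cat("<nichegraph config>\n")
  for (nm in names(x)) cat(sprintf("  %-21s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write / read a configuration as YAML
#'
#' @param config An [run_config()] object.
#' @param path File path.
#' @return `path` (write) or an `ng_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ng_assert(file.exists(path), paste0("file not found: ", path))
  do.call(run_config, yaml::read_yaml(path))
}
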