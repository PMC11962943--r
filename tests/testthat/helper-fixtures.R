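# small in-code fixtures used across the suite

`%||%` <- function(a, b) if (is.null(a)) b else a

make_cells <- function(x, y, phenotype, patient_id = "p1", image_id = "i1") {
  tibble::tibble(patient_id = patient_id, image_id = image_id,
                 x = x, y = y, phenotype = phenotype)
}

# two cells of distinct phenotypes separated by d micrometers
two_cell_patient <- function(d, phenotypes = c("a", "b")) {
  make_cells(x = c(0, d), y = c(0, 0), phenotype = phenotypes)
}

# a random single-image patient with uniform coordinates
random_patient <- function(n, m = 3, extent = 100, patient_id = "p1",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_cells(x = runif(n, 0, extent), y = runif(n, 0, extent),
             phenotype = sample(letters[seq_len(m)], n, replace = TRUE),
             patient_id = patient_id)
}

# small fast cohort for pipeline-level tests (clears min_cells = 1)
small_sim <- function(seed, n_patients = 12) {
  simulate_cohort(sim_config(
    n_patients = n_patients, n_subgroups = 3,
    niches_per_patient = 3, cells_per_niche = 25,
    niche_radius = 40, image_size = 600, min_separation = 150,
    background_rate = 5, seed = seed))
}

small_config <- function(seed = 1) {
  run_config(min_cells = 1, k_pheno = 30, k_star = 5, random_seed = seed)
}

# a binary graph object from an explicit adjacency matrix (for the WL
# comparator, which only reads $A and $phenotype)
binary_graph_from_matrix <- function(A, phenotype) {
  A <- A | t(A)
  diag(A) <- FALSE
  structure(list(A = A, phenotype = phenotype, cells = NULL,
                 threshold = NA, distance_cutoff = NA),
            class = "binary_graph")
}

ari <- function(a, b) {
  testthat::skip_if_not_installed("mclust")
  mclust::adjustedRandIndex(a, b)
}
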