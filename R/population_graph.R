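#' Build the patient-level population graph
#'
#' Starting from the kernel matrix, each patient's `k_star` most similar
#' other patients form its nearest-neighbor set (self excluded; similarity
#' ties break by patient index). The edge weight between two patients is then
#' the intersection-over-union (Jaccard index) of their neighbor sets, which
#' suppresses hub-driven spurious similarity before community detection.
#' Pairs with zero overlap carry no edge.
#'
#' @param K Symmetric kernel matrix with unit diagonal and patient ids as
#'   dimnames (see [kernel_matrix()]).
#' @param k_star Neighborhood size, `1 <= k_star < nrow(K)`; default 30.
#' @return An object of class `population_graph`: an `edges` tibble
#'   (`from`, `to`, `weight` with `from < to` by index), the patient ids, the
#'   `k_star` used, and the neighbor-set index matrix `nn`.
#' @export
build_population_graph <- function(K, k_star = 30) {
  ng_assert(is.matrix(K) && nrow(K) == ncol(K), "K must be a square matrix")
  ng_assert(max(abs(K - t(K))) < 1e-8, "K must be symmetric")
  n <- nrow(K)
  k_star <- as.integer(k_star)
  ng_assert(k_star >= 1 && k_star < n,
            "k_star must satisfy 1 <= k_star < number of patients")
  ids <- rownames(K) %||% as.character(seq_len(n))
  nn <- matrix(0L, n, k_star)
  for (i in seq_len(n)) {
    sim <- K[i, ]
    sim[i] <- -Inf                       # self excluded from the NN set
    ord <- order(-sim, seq_len(n))
    nn[i, ] <- ord[seq_len(k_star)]
  }
  B <- matrix(0L, n, n)
  B[cbind(rep(seq_len(n), k_star), as.vector(nn))] <- 1L
  inter <- tcrossprod(B)
  iou <- inter / (2 * k_star - inter)
  ut <- which(upper.tri(iou) & iou > 0, arr.ind = TRUE)
  edges <- tibble(from = ut[, 1], to = ut[, 2], weight = iou[ut])
  structure(list(edges = edges, patient_id = ids, k_star = k_star, nn = nn),
            class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  cat("<population_graph>", length(x$patient_id), "patients,",
      nrow(x$edges), "IoU edges (k* =", x$k_star, ")\n")
  if (!is.null(x$subgroup)) {
    cat("  subgroups:", paste(table(x$subgroup), collapse = " / "),
        "| modularity", signif(x$modularity, 4), "\n")
  }
  invisible(x)
}

#' Detect patient subgroups by Louvain community detection
#'
#' Runs Louvain modularity maximisation on the IoU-weighted population graph.
#' Communities are relabelled by descending size (ties by smallest patient
#' index) so subgroup 1 is always the largest, and the partition is
#' reproducible for a fixed seed.
#'
#' @param pop_graph A [build_population_graph()] result.
#' @param seed Integer seed; default 1.
#' @return The `population_graph` with `subgroup` (integer label per
#'   patient), `modularity`, and `seed` fields filled in.
#' @export
detect_communities <- function(pop_graph, seed = 1) {
  ng_assert(inherits(pop_graph, "population_graph"),
            "expected a population_graph")
  n <- length(pop_graph$patient_id)
  g <- igraph::graph_from_data_frame(
    pop_graph$edges, directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = 1)
  labels <- as.integer(igraph::membership(comm))[match(seq_len(n),
             as.integer(igraph::V(g)$name))]
  pop_graph$subgroup <- relabel_by_size(labels)
  pop_graph$modularity <- igraph::modularity(comm)
  pop_graph$seed <- as.integer(seed)
  pop_graph
}

#' Subgroup assignments as a tibble
#'
#' @param x A `population_graph` with communities detected.
#' @param ... Unused.
#' @return A tibble with `patient_id` and `subgroup`.
#' @export
tidy.population_graph <- function(x, ...) {
  ng_assert(!is.null(x$subgroup), "run detect_communities() first")
  tibble(patient_id = x$patient_id, subgroup = x$subgroup)
}

#' @export
glance.population_graph <- function(x, ...) {
  tibble(n_patients = length(x$patient_id),
         n_edges = nrow(x$edges),
         k_star = x$k_star,
         n_subgroups = if (is.null(x$subgroup)) NA_integer_
                       else max(x$subgroup),
         modularity = x$modularity %||% NA_real_)
}

#' Average inter-patient similarity within groups
#'
#' Mean of the kernel over unordered within-group pairs, plus the cohort-wide
#' mean over all pairs. Groups of a single patient have no pair and are
#' reported as `NA`.
#'
#' @param K Kernel matrix with patient-id dimnames.
#' @param grouping A data frame with `patient_id` and `group` columns.
#' @return A tibble with `group`, `n`, `mean_similarity`; the final row
#'   (`group = "(cohort)"`) is the mean over all patient pairs.
#' @export
group_similarity <- function(K, grouping) {
  ng_assert(all(c("patient_id", "group") %in% names(grouping)),
            "grouping needs patient_id and group columns")
  ids <- rownames(K)
  ng_assert(!is.null(ids), "K must carry patient ids as dimnames")
  grouping <- grouping[grouping$patient_id %in% ids, ]
  per_group <- grouping |>
    group_by(group = .data$group) |>
    summarise(n = n(),
              mean_similarity = mean_offdiag(K[.data$patient_id,
                                               .data$patient_id,
                                               drop = FALSE]),
              .groups = "drop") |>
    mutate(group = as.character(.data$group))
  all_ids <- grouping$patient_id
  bind_rows(per_group,
            tibble(group = "(cohort)", n = length(all_ids),
                   mean_similarity = mean_offdiag(K[all_ids, all_ids,
                                                    drop = FALSE])))
}

mean_offdiag <- function(M) {
  if (nrow(M) < 2) return(NA_real_)
  mean(M[upper.tri(M)])
}

#' Force-directed 3D layout of the population graph
#'
#' Cosmetic helper: Fruchterman-Reingold coordinates for plotting; carries no
#' analytic meaning.
#'
#' @param pop_graph A `population_graph`.
#' @param seed Integer seed; default 1.
#' @param dim 2 or 3; default 3.
#' @return A tibble with `patient_id` and coordinate columns.
#' @export
layout_population <- function(pop_graph, seed = 1, dim = 3) {
  ng_assert(inherits(pop_graph, "population_graph"),
            "expected a population_graph")
  n <- length(pop_graph$patient_id)
  g <- igraph::graph_from_data_frame(
    pop_graph$edges, directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, dim = dim)
  out <- as_tibble(as.data.frame(xy))
  names(out) <- c("x", "y", "z")[seq_len(dim)]
  bind_cols(tibble(patient_id = pop_graph$patient_id), out)
}
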