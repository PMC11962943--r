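#' Subtree feature embeddings by graph convolution
#'
#' Each cell roots a depth-`h` subtree whose levels are successive graph
#' neighborhoods. Because edges are continuous weights, isomorphism is the
#' wrong equivalence; instead every subtree is summarised by a feature
#' embedding computed with `h` sweeps of graph convolution. Starting from the
#' one-hot phenotype encoding `x_i(0)`, each sweep accumulates
#' `x_i <- x_i + sum_j x_j * A_ij` over the other cells; with unit self-loops
#' this equals the rows of `A^h %*% X0`. The embedding mixes the phenotype
#' composition of the neighborhood, weighted by spatial proximity.
#'
#' @param graph A [build_cellular_graph()] result.
#' @param h Subtree depth (number of sweeps), integer >= 1; default 2.
#' @param vocabulary A [phenotype_vocabulary()] fixing the column order; by
#'   default built from the graph's own cells.
#' @return A numeric matrix with one row per cell (in graph node order) and
#'   one column per vocabulary phenotype.
#' @export
compute_embeddings <- function(graph, h = 2, vocabulary = NULL) {
  ng_assert(inherits(graph, "cellular_graph"), "expected a cellular_graph")
  h <- as.integer(h)
  ng_assert(h >= 1, "h must be an integer >= 1")
  vocabulary <- if (is.null(vocabulary)) vocabulary_from_cells(graph$cells)
                else as_phenotype_vocabulary(vocabulary)
  X <- one_hot(graph$cells$phenotype, vocabulary)
  for (i in seq_len(h)) X <- as.matrix(graph$A %*% X)
  colnames(X) <- vocabulary$phenotype
  X
}

one_hot <- function(phenotype, vocabulary) {
  idx <- match(phenotype, vocabulary$phenotype)
  ng_assert(!anyNA(idx), "phenotype outside the vocabulary")
  m <- nrow(vocabulary)
  X <- matrix(0, nrow = length(phenotype), ncol = m,
              dimnames = list(NULL, vocabulary$phenotype))
  X[cbind(seq_along(idx), idx)] <- 1
  X
}

#' Pool subtree embeddings across a cohort
#'
#' Builds each patient's cellular graph and computes depth-`h` subtree
#' embeddings for every cell, returning one tidy tibble for the whole cohort.
#' Embedding columns are prefixed `emb_` and follow the vocabulary order.
#'
#' @param cells Cohort cell table.
#' @param vocabulary A [phenotype_vocabulary()]; default built from `cells`.
#' @param alpha Gaussian decay rate; default 0.01.
#' @param h Subtree depth; default 2.
#' @param sparsify_epsilon See [build_cellular_graph()].
#' @return A tibble with `patient_id`, `image_id`, `x`, `y`, `phenotype`, and
#'   `emb_*` columns, one row per cell (subtree root).
#' @export
compute_subtree_embeddings <- function(cells, vocabulary = NULL,
                                       alpha = 0.01, h = 2,
                                       sparsify_epsilon = 0) {
  cells <- validate_cell_table(cells)
  vocabulary <- if (is.null(vocabulary)) vocabulary_from_cells(cells)
                else as_phenotype_vocabulary(vocabulary)
  pieces <- cells |>
    split(~patient_id) |>
    purrr::map(function(pc) {
      g <- build_cellular_graph(pc, alpha = alpha,
                                sparsify_epsilon = sparsify_epsilon)
      E <- compute_embeddings(g, h = h, vocabulary = vocabulary)
      colnames(E) <- paste0("emb_", colnames(E))
      bind_cols(g$cells, as_tibble(E))
    })
  out <- bind_rows(pieces)
  attr(out, "vocabulary") <- vocabulary
  attr(out, "h") <- as.integer(h)
  attr(out, "alpha") <- alpha
  out
}

embedding_matrix <- function(embeddings) {
  cols <- grep("^emb_", names(embeddings), value = TRUE)
  ng_assert(length(cols) >= 1, "no emb_* columns found")
  E <- as.matrix(embeddings[cols])
  colnames(E) <- sub("^emb_", "", cols)
  E
}

#' Cellular-neighborhood membership of each subtree
#'
#' The neighborhood of a subtree has no sharp boundary; for reporting, a cell
#' `j` is counted as part of the neighborhood of root `i` when its influence
#' `(A^h)_ij` strictly exceeds `tau`. The root always belongs to its own
#' neighborhood (its diagonal influence is at least 1).
#'
#' @param graph A [build_cellular_graph()] result.
#' @param h Subtree depth; default 2.
#' @param tau Influence threshold; default 0.01.
#' @return A tibble with one row per cell: neighborhood `size`, `radius`
#'   (maximum centroid distance from root to a member, μm), and the member
#'   indices as a list-column. Cohort medians are attached as attributes
#'   `median_size`, `median_radius`.
#' @export
neighborhood_membership <- function(graph, h = 2, tau = 0.01) {
  ng_assert(inherits(graph, "cellular_graph"), "expected a cellular_graph")
  ng_assert(tau > 0, "tau must be > 0")
  Ah <- as.matrix(graph$A)
  if (h > 1) Ah <- matrix_power(Ah, h)
  members <- apply(Ah > tau, 1, which, simplify = FALSE)
  xs <- graph$cells$x; ys <- graph$cells$y
  radius <- purrr::map2_dbl(members, seq_along(members), function(mem, i) {
    if (length(mem) == 0) return(0)
    max(sqrt((xs[mem] - xs[i])^2 + (ys[mem] - ys[i])^2))
  })
  out <- tibble(cell = seq_len(nrow(graph$cells)),
                size = lengths(members), radius = radius,
                members = members)
  attr(out, "median_size") <- median(out$size)
  attr(out, "median_radius") <- median(out$radius)
  out
}

matrix_power <- function(A, h) {
  P <- A
  for (i in seq_len(h - 1)) P <- P %*% A
  P
}

#' Discover recurring patterns by clustering subtree embeddings
#'
#' Pools the subtree embeddings of the discovery cohort and clusters them in
#' the style of PhenoGraph: an exact Euclidean k-nearest-neighbor graph is
#' built over embedding rows, each k-NN edge is reweighted by the Jaccard
#' overlap (intersection over union) of the endpoints' neighbor sets, and
#' Louvain modularity communities of the resulting graph become the patterns.
#' Each pattern's signature is the centroid (arithmetic mean) of its member
#' embeddings. Neighbor ties break by (distance, row index); pattern labels
#' are renumbered by descending size, then smallest member row.
#'
#' @param embeddings A [compute_subtree_embeddings()] tibble (or any data
#'   frame with `emb_*` columns and a `patient_id` column).
#' @param k_pheno Number of nearest neighbors; default 100.
#' @param seed Integer seed controlling Louvain; required for reproducibility.
#' @param vocabulary Optional [phenotype_vocabulary()] used to categorise
#'   patterns; defaults to the vocabulary attribute of `embeddings`.
#' @param interface_cutoff Dominance share below which a pattern is called an
#'   interface niche; see [categorize_patterns()].
#' @param l1_normalize If `TRUE`, embedding rows are L1-normalised (to
#'   composition proportions) before the k-NN search, discarding
#'   neighborhood-density information. Default `FALSE`: embeddings are
#'   clustered raw, consistent with signatures being means of raw
#'   embeddings.
#' @return An object of class `pattern_model`: labels per subtree, the
#'   `C x m` signature matrix, pattern categories, the vocabulary, and the
#'   hyperparameters (including Louvain modularity).
#' @export
cluster_subtrees <- function(embeddings, k_pheno = 100, seed = 1,
                             vocabulary = NULL, interface_cutoff = 0.5,
                             l1_normalize = FALSE) {
  E <- embedding_matrix(embeddings)
  E_cluster <- if (l1_normalize) E / pmax(rowSums(abs(E)), 1e-300) else E
  n <- nrow(E)
  k_pheno <- as.integer(k_pheno)
  ng_assert(n >= k_pheno + 1,
            paste0("need at least k_pheno + 1 = ", k_pheno + 1,
                   " pooled subtrees, got ", n))
  vocabulary <- vocabulary %||% attr(embeddings, "vocabulary") %||%
    phenotype_vocabulary(colnames(E))
  vocabulary <- as_phenotype_vocabulary(vocabulary)

  nn <- knn_index(E_cluster, k_pheno)
  ed <- jaccard_edges(nn)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$i, to = ed$j, weight = ed$weight),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = 1)
  labels <- as.integer(igraph::membership(comm))
  labels <- relabel_by_size(labels)
  sig <- compute_signatures(E, labels)
  model <- structure(list(
    labels = labels,
    signatures = sig,
    vocabulary = vocabulary,
    patient_id = if ("patient_id" %in% names(embeddings))
      embeddings$patient_id else NULL,
    hyperparameters = list(
      k_pheno = k_pheno, seed = as.integer(seed),
      h = attr(embeddings, "h"), alpha = attr(embeddings, "alpha"),
      l1_normalize = l1_normalize,
      modularity = igraph::modularity(comm)),
    categories = NULL
  ), class = "pattern_model")
  if (!all(is.na(vocabulary$category))) {
    model$categories <- categorize_patterns(model,
                                            interface_cutoff = interface_cutoff)
  }
  model
}

# exact Euclidean k-NN (self excluded), blocked so no n x n matrix is formed;
# ties broken by (distance, row index)
knn_index <- function(E, k) {
  n <- nrow(E)
  sq <- rowSums(E^2)
  idx <- matrix(0L, n, k)
  block <- max(1L, min(n, as.integer(2^22 / n)))
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    rows <- s:min(s + block - 1L, n)
    D2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(E[rows, , drop = FALSE], E)
    D2[cbind(seq_along(rows), rows)] <- Inf
    D2[D2 < 0] <- 0
    for (r in seq_along(rows)) {
      d <- D2[r, ]
      # partial selection before the full ordering of the short candidate set
      kth <- sort(d, partial = k)[k]
      cand <- which(d <= kth)
      idx[rows[r], ] <- cand[order(d[cand], cand)][seq_len(k)]
    }
  }
  idx
}

# Jaccard overlap of k-NN sets for every undirected k-NN edge
jaccard_edges <- function(nn) {
  n <- nrow(nn); k <- ncol(nn)
  ei <- rep(seq_len(n), k); ej <- as.vector(nn)
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  keep <- !duplicated(lo + (hi - 1) * n)
  lo <- lo[keep]; hi <- hi[keep]
  B <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  inter <- numeric(length(lo))
  block <- 20000L
  for (s in seq(1L, length(lo), by = block)) {
    sel <- s:min(s + block - 1L, length(lo))
    inter[sel] <- Matrix::rowSums(B[lo[sel], , drop = FALSE] *
                                  B[hi[sel], , drop = FALSE])
  }
  weight <- inter / (2 * k - inter)
  keep2 <- weight > 0
  list(i = lo[keep2], j = hi[keep2], weight = weight[keep2])
}

relabel_by_size <- function(labels) {
  size <- table(labels)
  first <- tapply(seq_along(labels), labels, min)
  ord <- order(-as.vector(size), as.vector(first))
  old <- as.integer(names(size))[ord]
  match(labels, old)
}

#' Pattern signatures (cluster centroids)
#'
#' @param embeddings Embedding matrix (rows = subtrees) or a tibble with
#'   `emb_*` columns.
#' @param labels Integer pattern label per subtree, values in `1..C`.
#' @return A `C x m` matrix; row `c` is the mean embedding of pattern `c`.
#' @export
compute_signatures <- function(embeddings, labels) {
  E <- if (is.matrix(embeddings)) embeddings else embedding_matrix(embeddings)
  ng_assert(length(labels) == nrow(E), "one label per embedding row required")
  C <- max(labels)
  counts <- tabulate(labels, nbins = C)
  ng_assert(all(counts > 0), "every pattern label in 1..C must be non-empty")
  S <- rowsum(E, labels) / counts
  rownames(S) <- paste0("P", seq_len(C))
  S
}

#' Per-patient pattern histograms
#'
#' Every cell roots exactly one subtree, so a patient's histogram of pattern
#' labels sums to the patient's cell count.
#'
#' @param assignments A data frame with columns `patient_id` and `pattern`
#'   (integer labels in `1..C`).
#' @param C Number of patterns; default `max(pattern)`.
#' @return A tibble with `patient_id` and one count column per pattern
#'   (`P1..PC`), one row per patient.
#' @export
pattern_histograms <- function(assignments, C = max(assignments$pattern)) {
  ng_assert(all(c("patient_id", "pattern") %in% names(assignments)),
            "need columns patient_id and pattern")
  ng_assert(all(assignments$pattern >= 1 & assignments$pattern <= C),
            "pattern labels must lie in 1..C")
  counts <- assignments |>
    count(.data$patient_id, .data$pattern) |>
    mutate(pattern = factor(paste0("P", .data$pattern),
                            levels = paste0("P", seq_len(C)))) |>
    tidyr::pivot_wider(names_from = "pattern", values_from = "n",
                       values_fill = 0L, names_expand = TRUE)
  counts[c("patient_id", paste0("P", seq_len(C)))]
}

#' Model and pattern assignments in one step
#'
#' Convenience wrapper returning the per-subtree assignment tibble of a
#' fitted [cluster_subtrees()] model.
#'
#' @param model A `pattern_model`.
#' @param embeddings The embeddings tibble the model was fitted on.
#' @return `embeddings` with a `pattern` column appended.
#' @export
pattern_assignments <- function(model, embeddings) {
  ng_assert(inherits(model, "pattern_model"), "expected a pattern_model")
  ng_assert(length(model$labels) == nrow(embeddings),
            "model was fitted on a different number of subtrees")
  mutate(as_tibble(embeddings), pattern = model$labels)
}

#' Soft-WL kernel: cosine similarity of pattern histograms
#'
#' The similarity of two patients is the normalized inner product of their
#' pattern histograms, so it lies in `[0, 1]` and identical histograms score
#' exactly 1.
#'
#' @param phi_i,phi_j Nonnegative numeric histogram vectors of equal length,
#'   each with at least one positive entry.
#' @return A similarity in `[0, 1]`.
#' @export
softwl_similarity <- function(phi_i, phi_j) {
  ng_assert(length(phi_i) == length(phi_j), "histograms differ in length")
  ni <- sqrt(sum(phi_i^2)); nj <- sqrt(sum(phi_j^2))
  ng_assert(ni > 0 && nj > 0, "all-zero histogram has no defined similarity")
  if (identical(as.numeric(phi_i), as.numeric(phi_j))) return(1)
  min(1, max(0, sum(phi_i * phi_j) / (ni * nj)))
}

#' Kernel matrix over patient profiles
#'
#' @param profiles A [pattern_histograms()] tibble (`patient_id` + count
#'   columns), or a numeric matrix with patient row names.
#' @return A symmetric kernel matrix with unit diagonal, entries in `[0,1]`,
#'   dimnames = patient ids.
#' @export
kernel_matrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    M <- as.matrix(profiles[setdiff(names(profiles), "patient_id")])
    rownames(M) <- profiles$patient_id
  } else {
    M <- as.matrix(profiles)
  }
  nrm <- sqrt(rowSums(M^2))
  ng_assert(all(nrm > 0), "every patient needs a nonzero histogram")
  K <- tcrossprod(M / nrm)
  K[K > 1] <- 1; K[K < 0] <- 0
  diag(K) <- 1
  K
}
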