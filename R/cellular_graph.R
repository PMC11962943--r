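#' Build a patient's Gaussian-weighted cellular graph
#'
#' Every pair of cells within one image is connected with weight
#' `w_ij = exp(-alpha * d_ij^2)`, where `d_ij` is the Euclidean distance
#' between the two cell centroids in micrometers, so interaction strength
#' decays smoothly with distance. Self-loops of weight 1 are added (the
#' adjacency diagonal is all 1). When a patient has several images (e.g.
#' multiple tissue-microarray cores), the images enter as disconnected
#' components of one larger graph: cross-image weights are exactly 0.
#'
#' @param cells Cell table restricted to a single patient (at least one row).
#' @param alpha Decay rate of the Gaussian kernel (1/μm²); default 0.01.
#' @param sparsify_epsilon Weights below this cutoff are stored as exact
#'   zeros. The default 0 keeps the exact dense complete graph; a small
#'   cutoff (e.g. 1e-6) is an efficiency option for very large images.
#' @return An object of class `cellular_graph`: a list with the symmetric
#'   adjacency `A` (a `Matrix::dsCMatrix` with unit diagonal), the `cells`
#'   tibble in node order, and the parameters used.
#' @examples
#' cells <- tibble::tibble(patient_id = "p1", image_id = "i1",
#'                         x = c(0, 3), y = c(0, 0),
#'                         phenotype = c("a", "b"))
#' g <- build_cellular_graph(cells)
#' g$A[1, 2]  # exp(-0.01 * 9) > 0.9
#' @export
build_cellular_graph <- function(cells, alpha = 0.01, sparsify_epsilon = 0) {
  cells <- validate_cell_table(cells)
  ng_assert(nrow(cells) >= 1, "cellular graph needs at least one cell")
  ng_assert(length(unique(cells$patient_id)) == 1,
            "build_cellular_graph expects cells from a single patient")
  ng_assert(alpha > 0, "alpha must be > 0")
  # stable image order: first appearance; node order = row order within image
  img <- factor(cells$image_id, levels = unique(cells$image_id))
  ord <- order(img, seq_len(nrow(cells)))
  cells <- cells[ord, ]
  blocks <- lapply(split(seq_len(nrow(cells)), cells$image_id)[unique(cells$image_id)],
                   function(idx) {
    W <- gaussian_weights(cells$x[idx], cells$y[idx], alpha)
    if (sparsify_epsilon > 0) W[W < sparsify_epsilon] <- 0
    diag(W) <- 1
    W
  })
  A <- if (length(blocks) == 1L) {
    methods::as(methods::as(Matrix::Matrix(blocks[[1]], sparse = TRUE), "symmetricMatrix"), "CsparseMatrix")
  } else {
    methods::as(Matrix::forceSymmetric(Matrix::bdiag(blocks)), "CsparseMatrix")
  }
  structure(list(A = A, cells = cells, alpha = alpha,
                 sparsify_epsilon = sparsify_epsilon),
            class = "cellular_graph")
}

gaussian_weights <- function(x, y, alpha) {
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  exp(-alpha * d2)
}

#' @export
print.cellular_graph <- function(x, ...) {
  cat("<cellular_graph> patient", unique(x$cells$patient_id),
      "|", nrow(x$cells), "cells in", length(unique(x$cells$image_id)),
      "image(s) | alpha =", x$alpha, "\n")
  invisible(x)
}

#' Binarize a cellular graph for the classic WL comparator
#'
#' Keeps an (off-diagonal) edge whenever its Gaussian weight is at least
#' `threshold`; self-loops are dropped. At the defaults (`alpha = 0.01`,
#' `threshold = 0.01`) this connects cells whose centroids are at most 21 μm
#' apart: `exp(-0.01 * 21^2) = 0.0122 >= 0.01` while a 22 μm pair falls to
#' `0.0079 < 0.01`.
#'
#' @param graph A [build_cellular_graph()] result.
#' @param threshold Edge-weight cutoff in (0,1); default 0.01.
#' @return A list of class `binary_graph` with the logical sparse adjacency
#'   `A` (no self-loops), the node `phenotype` vector, `cells`, and the
#'   equivalent centroid-distance cutoff `distance_cutoff` in μm.
#' @export
binarize_graph <- function(graph, threshold = 0.01) {
  ng_assert(inherits(graph, "cellular_graph"), "expected a cellular_graph")
  ng_assert(threshold > 0 && threshold < 1, "threshold must be in (0,1)")
  A <- graph$A
  B <- A >= threshold
  Matrix::diag(B) <- FALSE
  B <- methods::as(B, "CsparseMatrix")
  cutoff <- sqrt(log(1 / threshold) / graph$alpha)
  inform(sprintf(
    "binarize_graph: weight threshold %.4g keeps edges up to %.2f um between centroids",
    threshold, cutoff))
  structure(list(A = B, phenotype = graph$cells$phenotype,
                 cells = graph$cells, threshold = threshold,
                 distance_cutoff = cutoff),
            class = "binary_graph")
}
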