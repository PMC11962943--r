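#' Cell-phenotype abundance profiles
#'
#' The simplest comparator representation: each patient is the histogram of
#' its cell phenotypes, ignoring all spatial structure.
#'
#' @param cells Cohort cell table.
#' @param vocabulary A [phenotype_vocabulary()] fixing column order; default
#'   built from `cells`.
#' @return A tibble with `patient_id` and one count column per phenotype.
#' @export
cell_abundance_profiles <- function(cells, vocabulary = NULL) {
  cells <- validate_cell_table(cells)
  vocabulary <- if (is.null(vocabulary)) vocabulary_from_cells(cells)
                else as_phenotype_vocabulary(vocabulary)
  cells |>
    count(.data$patient_id,
          phenotype = factor(.data$phenotype,
                             levels = vocabulary$phenotype)) |>
    tidyr::pivot_wider(names_from = "phenotype", values_from = "n",
                       values_fill = 0L, names_expand = TRUE)
}

#' Pairwise phenotype-proximity profiles
#'
#' For every unordered pair of distinct phenotypes (a, b), the average
#' Gaussian proximity `exp(-alpha * d^2)` over all cross-phenotype cell
#' pairs within the same image. A pair with no co-occurring cells gets 0 (and
#' a note), keeping the cosine kernel defined.
#'
#' @param cells Cohort cell table.
#' @param vocabulary Optional [phenotype_vocabulary()].
#' @param alpha Gaussian decay rate; default 0.01.
#' @return A tibble with `patient_id` and one column per phenotype pair
#'   (named `a|b` in vocabulary order), `m(m-1)/2` feature columns.
#' @export
pairwise_proximity_profiles <- function(cells, vocabulary = NULL,
                                        alpha = 0.01) {
  cells <- validate_cell_table(cells)
  vocabulary <- if (is.null(vocabulary)) vocabulary_from_cells(cells)
                else as_phenotype_vocabulary(vocabulary)
  ph <- vocabulary$phenotype
  m <- length(ph)
  pair_names <- utils::combn(ph, 2, FUN = paste, collapse = "|")
  per_patient <- purrr::map_dfr(split(cells, cells$patient_id), function(pc) {
    sums <- matrix(0, m, m, dimnames = list(ph, ph))
    npairs <- matrix(0, m, m, dimnames = list(ph, ph))
    for (ic in split(pc, pc$image_id)) {
      idx <- match(ic$phenotype, ph)
      W <- gaussian_weights(ic$x, ic$y, alpha)
      for (a in seq_len(m - 1)) {
        ra <- which(idx == a)
        if (!length(ra)) next
        for (b in (a + 1):m) {
          rb <- which(idx == b)
          if (!length(rb)) next
          sums[a, b] <- sums[a, b] + sum(W[ra, rb, drop = FALSE])
          npairs[a, b] <- npairs[a, b] + length(ra) * length(rb)
        }
      }
    }
    prox <- ifelse(npairs > 0, sums / pmax(npairs, 1), 0)
    pairs <- t(utils::combn(m, 2))
    vals <- prox[pairs]
    out <- as_tibble(as.list(setNames(vals, pair_names)))
    mutate(out, patient_id = pc$patient_id[1], .before = 1)
  })
  empties <- colSums(per_patient[pair_names] == 0)
  if (any(empties == nrow(per_patient))) {
    inform(paste0("pairwise_proximity_profiles: pair(s) never co-occurring ",
                  "set to 0: ",
                  paste(pair_names[empties == nrow(per_patient)],
                        collapse = ", ")))
  }
  per_patient
}

#' Niche-category abundance profiles
#'
#' Coarsens the pattern histogram to the four niche categories (tumor,
#' immune, stromal, interface): each patient is described by how many of its
#' subtrees fall in patterns of each category.
#'
#' @param assignments A data frame with `patient_id` and `pattern` labels.
#' @param categories A [categorize_patterns()] tibble (`pattern`,
#'   `category`).
#' @return A tibble with `patient_id` and columns `tumor`, `immune`,
#'   `stromal`, `interface`.
#' @export
category_abundance_profiles <- function(assignments, categories) {
  ng_assert(all(c("pattern", "category") %in% names(categories)),
            "categories needs pattern and category columns")
  lev <- c("tumor", "immune", "stromal", "interface")
  cat_of <- setNames(categories$category, categories$pattern)
  lab <- cat_of[paste0("P", assignments$pattern)]
  ng_assert(!anyNA(lab), "pattern label without a category")
  tibble(patient_id = assignments$patient_id,
         category = factor(lab, levels = lev)) |>
    count(.data$patient_id, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L, names_expand = TRUE)
}

#' Weisfeiler-Lehman color refinement across a cohort of binary graphs
#'
#' Classic WL refinement: the initial color of a node is its phenotype; at
#' each iteration a node's new color is a relabelling of the pair (own color,
#' sorted multiset of neighbor colors). The relabel table is shared across
#' all graphs so that identical depth-h rooted subtrees receive identical
#' colors cohort-wide, and new colors never reuse earlier ones.
#'
#' @param graphs A list of [binarize_graph()] results (or a single one).
#' @param h Number of refinement iterations; default 2.
#' @return An object of class `wl_colors`: per graph an `n x (h+1)` integer
#'   color matrix (iteration 0..h), plus `n_colors`, the per-iteration color
#'   id ranges, and `h`.
#' @export
wl_color_refinement <- function(graphs, h = 2) {
  if (inherits(graphs, "binary_graph")) graphs <- list(graphs)
  ng_assert(all(vapply(graphs, inherits, logical(1), "binary_graph")),
            "graphs must come from binarize_graph()")
  h <- as.integer(h)
  ng_assert(h >= 0, "h must be >= 0")
  phen <- lapply(graphs, function(g) g$phenotype)
  alphabet <- sort(unique(unlist(phen)))
  colors <- lapply(phen, function(p) matrix(match(p, alphabet), ncol = 1))
  next_color <- length(alphabet)
  ranges <- list(c(1L, length(alphabet)))
  adj <- lapply(graphs, function(g)
    lapply(seq_len(nrow(g$A)), function(i) which(g$A[i, ])))
  for (it in seq_len(h)) {
    keys <- purrr::map2(colors, adj, function(cm, nb) {
      cur <- cm[, it]
      vapply(seq_along(nb), function(i) {
        paste(cur[i], paste(sort(cur[nb[[i]]]), collapse = ","), sep = "|")
      }, character(1))
    })
    tab <- unique(unlist(keys))
    colors <- purrr::map2(colors, keys, function(cm, k) {
      cbind(cm, next_color + match(k, tab))
    })
    ranges[[it + 1]] <- c(next_color + 1L, next_color + length(tab))
    next_color <- next_color + length(tab)
  }
  structure(list(colors = colors, h = h, n_colors = next_color,
                 ranges = ranges, alphabet = alphabet),
            class = "wl_colors")
}

#' WL subtree-kernel feature profiles
#'
#' Counts color occurrences per graph: `"accumulated"` concatenates the
#' counts from iterations `0..h` (the standard WL subtree feature map);
#' `"last"` keeps only the colors of the final iteration, a stricter variant
#' under which two graphs are similar only if their deepest subtrees match.
#'
#' @param wl A [wl_color_refinement()] result.
#' @param mode `"accumulated"` or `"last"`.
#' @param patient_id Optional ids, one per graph; default `g1, g2, ...`.
#' @return A tibble with `patient_id` and one count column per color.
#' @export
wl_features <- function(wl, mode = c("accumulated", "last"),
                        patient_id = NULL) {
  ng_assert(inherits(wl, "wl_colors"), "expected wl_color_refinement() output")
  mode <- match.arg(mode)
  iters <- if (mode == "accumulated") seq_len(wl$h + 1) else wl$h + 1
  ids <- patient_id %||% paste0("g", seq_along(wl$colors))
  cols_used <- sort(unique(unlist(lapply(wl$colors, function(cm)
    as.vector(cm[, iters, drop = FALSE])))))
  M <- t(vapply(wl$colors, function(cm) {
    tab <- tabulate(match(as.vector(cm[, iters, drop = FALSE]), cols_used),
                    nbins = length(cols_used))
    as.numeric(tab)
  }, numeric(length(cols_used))))
  if (length(wl$colors) == 1L) M <- matrix(M, nrow = 1)
  colnames(M) <- paste0("c", cols_used)
  bind_cols(tibble(patient_id = ids), as_tibble(M))
}
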