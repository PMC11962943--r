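#' Normalize pattern histograms to per-patient proportions
#'
#' Divides each pattern count by the patient's total so rows sum to 1,
#' removing the (often large) differences in cells per patient before any
#' between-patient comparison.
#'
#' @param profiles A [pattern_histograms()] tibble.
#' @return A tibble of the same shape with proportions instead of counts.
#' @export
normalize_histograms <- function(profiles) {
  cols <- setdiff(names(profiles), "patient_id")
  M <- as.matrix(profiles[cols])
  tot <- rowSums(M)
  ng_assert(all(tot > 0), "every patient needs at least one cell")
  out <- as_tibble(M / tot)
  bind_cols(profiles["patient_id"], out)
}

#' Hodges-Lehmann statistic
#'
#' The median of all pairwise differences `x - y` over the full
#' `|x| * |y|` grid: a robust location shift between two samples. Positive
#' values mean `x` tends to exceed `y`.
#'
#' @param x,y Nonempty numeric samples.
#' @return The median pairwise difference (even-sized grids average the two
#'   central order statistics, as `median()` does).
#' @export
hodges_lehmann <- function(x, y) {
  ng_assert(length(x) >= 1 && length(y) >= 1, "both samples must be nonempty")
  median(outer(x, y, "-"))
}

#' Identify characteristic patterns per subgroup
#'
#' For each subgroup and pattern, compares the per-patient pattern
#' proportions inside versus outside the subgroup with the Hodges-Lehmann
#' statistic; a pattern is characteristic of the subgroup when its statistic
#' strictly exceeds `hl_fraction` of the subgroup's maximum statistic.
#' Subgroups whose maximum statistic is not positive select nothing (with a
#' warning): no pattern is enriched there.
#'
#' @param proportions A [normalize_histograms()] tibble.
#' @param subgroups A data frame with `patient_id` and `subgroup`.
#' @param hl_fraction Fraction of the subgroup maximum; default 0.5.
#' @return A tibble with one row per (subgroup, pattern): `hl` statistic,
#'   subgroup `max_hl`, the selection `threshold`, and logical `selected`.
#' @export
characteristic_patterns <- function(proportions, subgroups,
                                    hl_fraction = 0.5) {
  ng_assert(hl_fraction > 0 && hl_fraction <= 1,
            "hl_fraction must be in (0,1]")
  merged <- inner_join(proportions, subgroups, by = "patient_id")
  ng_assert(nrow(merged) > 0, "no overlapping patients")
  pats <- setdiff(names(proportions), "patient_id")
  groups <- sort(unique(merged$subgroup))
  ng_assert(length(groups) >= 2,
            "need at least two subgroups to compare inside vs outside")
  out <- purrr::map_dfr(groups, function(g) {
    inside <- merged[merged$subgroup == g, ]
    outside <- merged[merged$subgroup != g, ]
    hl <- vapply(pats, function(p) {
      hodges_lehmann(inside[[p]], outside[[p]])
    }, numeric(1))
    tibble(subgroup = g, pattern = pats, hl = unname(hl))
  })
  out <- out |>
    group_by(.data$subgroup) |>
    mutate(max_hl = max(.data$hl),
           threshold = hl_fraction * .data$max_hl,
           selected = .data$max_hl > 0 & .data$hl > .data$threshold) |>
    ungroup()
  degenerate <- unique(out$subgroup[out$max_hl <= 0])
  if (length(degenerate)) {
    warn(paste0("no pattern is enriched in subgroup(s) ",
                paste(degenerate, collapse = ", "),
                " (maximum Hodges-Lehmann statistic <= 0)"))
  }
  out
}

#' Categorize patterns into niche classes
#'
#' Sums each pattern signature's mass over the tumor / immune / stromal
#' phenotype categories. The pattern is called after the dominant category
#' when that category's share reaches `interface_cutoff`; otherwise the cell
#' types are considered mixed and the pattern is an `interface` niche.
#'
#' @param model A `pattern_model` (or a signature matrix, in which case
#'   `vocabulary` must be given).
#' @param vocabulary A [phenotype_vocabulary()] with categories assigned.
#' @param interface_cutoff Dominance share in (0,1]; default 0.5. The
#'   boundary counts as dominant (`>=`).
#' @return A tibble with `pattern`, per-category shares, and `category` in
#'   `{tumor, immune, stromal, interface}`.
#' @export
categorize_patterns <- function(model, vocabulary = NULL,
                                interface_cutoff = 0.5) {
  if (inherits(model, "pattern_model")) {
    S <- model$signatures
    vocabulary <- vocabulary %||% model$vocabulary
  } else {
    S <- as.matrix(model)
  }
  ng_assert(!is.null(vocabulary), "a vocabulary with categories is required")
  vocabulary <- as_phenotype_vocabulary(vocabulary)
  ng_assert(!anyNA(vocabulary$category),
            "every phenotype needs a tumor/immune/stromal category")
  ng_assert(ncol(S) == nrow(vocabulary),
            "signature columns must match the vocabulary")
  cats <- c("tumor", "immune", "stromal")
  mass <- vapply(cats, function(ct) {
    cols <- vocabulary$category == ct
    if (!any(cols)) return(rep(0, nrow(S)))
    rowSums(S[, cols, drop = FALSE])
  }, numeric(nrow(S)))
  if (nrow(S) == 1L) mass <- matrix(mass, nrow = 1, dimnames = list(NULL, cats))
  tot <- rowSums(mass)
  ng_assert(all(tot > 0), "zero-mass signature cannot be categorized")
  share <- mass / tot
  top <- max.col(share, ties.method = "first")
  category <- ifelse(share[cbind(seq_len(nrow(S)), top)] >= interface_cutoff,
                     cats[top], "interface")
  tibble(pattern = rownames(S) %||% paste0("P", seq_len(nrow(S))),
         tumor = unname(share[, "tumor"]),
         immune = unname(share[, "immune"]),
         stromal = unname(share[, "stromal"]),
         category = unname(category))
}

#' Stratify patients by expression of one pattern
#'
#' Splits the cohort into pattern-positive (proportion at or above
#' `positivity_threshold`) and pattern-negative patients, the partition used
#' when testing the prognostic value of a single pattern.
#'
#' @param proportions A [normalize_histograms()] tibble.
#' @param pattern Pattern column name (e.g. `"P3"`).
#' @param positivity_threshold Default 0.01 (1% of the patient's cells).
#' @return A tibble with `patient_id`, `proportion`, and logical `positive`.
#' @export
stratify_by_pattern <- function(proportions, pattern,
                                positivity_threshold = 0.01) {
  ng_assert(pattern %in% names(proportions),
            paste0("unknown pattern: ", pattern))
  out <- tibble(patient_id = proportions$patient_id,
                proportion = proportions[[pattern]],
                positive = proportions[[pattern]] >= positivity_threshold)
  if (all(out$positive) || !any(out$positive)) {
    warn(paste0("stratify_by_pattern: all patients are on one side of the ",
                positivity_threshold, " threshold for ", pattern))
  }
  out
}
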