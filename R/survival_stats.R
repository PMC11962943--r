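#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates of the survival function for each patient group,
#' delegated to [survival::survfit()] and returned tidy for plotting.
#'
#' @param clinical A clinical tibble (`patient_id`, `survival_time`,
#'   `event`).
#' @param grouping A data frame with `patient_id` and `group`; patients
#'   missing from it are dropped.
#' @return A tibble with `group`, `time`, `n_risk`, `n_event`, `estimate`
#'   (the survival probability), starting at estimate 1.
#' @export
km_estimate <- function(clinical, grouping) {
  d <- survival_frame(clinical, grouping)
  out <- purrr::map_dfr(split(d, d$group), function(gd) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = gd)
    tibble(group = gd$group[1],
           time = c(0, fit$time),
           n_risk = c(fit$n, fit$n.risk),
           n_event = c(0, fit$n.event),
           estimate = c(1, fit$surv))
  })
  out
}

survival_frame <- function(clinical, grouping) {
  clinical <- validate_clinical_table(clinical)
  ng_assert(all(c("patient_id", "group") %in% names(grouping)),
            "grouping needs patient_id and group columns")
  d <- inner_join(
    tibble(patient_id = clinical$patient_id,
           time = clinical$survival_time, event = clinical$event),
    as_tibble(grouping)[c("patient_id", "group")],
    by = "patient_id")
  d <- d[stats::complete.cases(d[c("time", "event")]), ]
  ng_assert(nrow(d) > 0, "no patients with usable survival data")
  ng_assert(all(table(d$group) > 0), "every group must be nonempty")
  d
}

#' Multivariate (G-sample) log-rank test
#'
#' Compares the survival curves of all groups at once with the standard
#' G-sample log-rank test ([survival::survdiff()]); with two groups this is
#' the usual pairwise log-rank test.
#'
#' @inheritParams km_estimate
#' @return A one-row tibble: `statistic` (chi-square), `df` (G - 1),
#'   `p.value`, `n`, `n_groups`.
#' @export
multivariate_logrank <- function(clinical, grouping) {
  d <- survival_frame(clinical, grouping)
  ng_assert(length(unique(d$group)) >= 2, "need at least two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd$n) - 1
  tibble(statistic = unname(sd$chisq), df = df,
         p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
         n = nrow(d), n_groups = length(sd$n))
}

#' Per-subgroup Cox hazard ratios (subgroup vs rest)
#'
#' For each subgroup, fits a univariate Cox proportional-hazards model with a
#' single binary covariate (membership in that subgroup), patients outside
#' the subgroup serving as the baseline. Ties are handled with the Efron
#' approximation; the p-value is the log-likelihood-ratio test of the fit,
#' and the 95% CI is the Wald interval on the log hazard. Subgroups for which
#' the model is not estimable (e.g. one side has no events) are reported with
#' `NA` estimates rather than failing.
#'
#' @param clinical A clinical tibble.
#' @param subgroups A data frame with `patient_id` and `subgroup`.
#' @return A tibble with one row per subgroup: `subgroup`, `n`, `n_events`,
#'   `hr`, `conf.low`, `conf.high`, `p.value`, `note`.
#' @export
cox_subgroup_hr <- function(clinical, subgroups) {
  grouping <- tibble(patient_id = subgroups$patient_id,
                     group = subgroups$subgroup)
  d <- survival_frame(clinical, grouping)
  purrr::map_dfr(sort(unique(d$group)), function(s) {
    d$ind <- as.integer(d$group == s)
    base <- tibble(subgroup = s, n = sum(d$ind),
                   n_events = sum(d$event[d$ind == 1]))
    ng_assert(any(d$ind == 0),
              paste0("subgroup ", s, " contains every patient: ",
                     "no baseline group to compare against"))
    if (sum(d$event[d$ind == 1]) == 0 || sum(d$event[d$ind == 0]) == 0) {
      return(mutate(base, hr = NA_real_, conf.low = NA_real_,
                    conf.high = NA_real_, p.value = NA_real_,
                    note = "no events in one arm"))
    }
    fit <- survival::coxph(survival::Surv(time, event) ~ ind, data = d,
                           ties = "efron")
    ci <- exp(stats::confint(fit, level = 0.95))
    lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
    mutate(base, hr = unname(exp(stats::coef(fit))),
           conf.low = ci[1], conf.high = ci[2],
           p.value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
           note = NA_character_)
  })
}

#' Pairwise log-rank tests between all subgroups
#'
#' @param clinical A clinical tibble.
#' @param subgroups A data frame with `patient_id` and `subgroup`.
#' @return A tibble with one row per unordered subgroup pair and the two-
#'   group log-rank `statistic` and `p.value`. No multiplicity correction is
#'   applied.
#' @export
pairwise_logrank <- function(clinical, subgroups) {
  grouping <- tibble(patient_id = subgroups$patient_id,
                     group = subgroups$subgroup)
  d <- survival_frame(clinical, grouping)
  gs <- sort(unique(d$group))
  ng_assert(length(gs) >= 2, "need at least two subgroups")
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    dd <- d[d$group %in% pr, ]
    res <- multivariate_logrank(
      tibble(patient_id = dd$patient_id, survival_time = dd$time,
             event = dd$event),
      tibble(patient_id = dd$patient_id, group = dd$group))
    tibble(group1 = pr[1], group2 = pr[2],
           statistic = res$statistic, p.value = res$p.value)
  })
}

#' Associations between subgroups and clinical variables
#'
#' One-hot encodes subgroup membership and each categorical clinical
#' variable, then reports Spearman rank correlations (two-sided) between
#' every subgroup indicator and every clinical indicator or numeric
#' variable. Missing clinical values are dropped pairwise; constant vectors
#' yield `NA` with a note.
#'
#' @param subgroups A data frame with `patient_id` and `subgroup`.
#' @param clinical A clinical tibble; every column other than `patient_id`,
#'   `survival_time`, `event` is treated as a clinical variable.
#' @param variables Optional character vector restricting the clinical
#'   variables tested.
#' @return A tibble with `subgroup`, `variable`, `level` (NA for numeric
#'   variables), `rho`, `p.value`, `n`.
#' @export
associate_with_clinical <- function(subgroups, clinical, variables = NULL) {
  clinical <- as_tibble(clinical)
  merged <- inner_join(as_tibble(subgroups)[c("patient_id", "subgroup")],
                       clinical, by = "patient_id")
  ng_assert(nrow(merged) >= 3, "need at least 3 overlapping patients")
  vars <- variables %||%
    setdiff(names(clinical), c("patient_id", "survival_time", "event"))
  gs <- sort(unique(merged$subgroup))
  out <- list()
  for (g in gs) {
    ind <- as.integer(merged$subgroup == g)
    for (v in vars) {
      col <- merged[[v]]
      if (is.numeric(col)) {
        out[[length(out) + 1]] <-
          spearman_row(g, v, NA_character_, ind, col)
      } else {
        for (lev in sort(unique(stats::na.omit(as.character(col))))) {
          out[[length(out) + 1]] <-
            spearman_row(g, v, lev, ind,
                         as.integer(as.character(col) == lev))
        }
      }
    }
  }
  bind_rows(out)
}

spearman_row <- function(g, v, lev, ind, y) {
  ok <- stats::complete.cases(ind, y)
  ind <- ind[ok]; y <- y[ok]
  if (length(ind) < 3 || length(unique(ind)) < 2 || length(unique(y)) < 2) {
    return(tibble(subgroup = g, variable = v, level = lev,
                  rho = NA_real_, p.value = NA_real_, n = length(ind)))
  }
  ct <- suppressWarnings(
    stats::cor.test(ind, y, method = "spearman", exact = FALSE))
  tibble(subgroup = g, variable = v, level = lev,
         rho = unname(ct$estimate), p.value = ct$p.value, n = length(ind))
}

#' Mann-Whitney U comparison of a quantity between two patient sets
#'
#' Thin wrapper over [stats::wilcox.test()] reporting the U statistic of the
#' first sample and the two-sided p-value; used e.g. to compare pattern
#' proportions between responders and non-responders.
#'
#' @param x,y Numeric samples.
#' @return A one-row tibble with `statistic` (U for `x`), `p.value`, `n_x`,
#'   `n_y`.
#' @export
mann_whitney_u <- function(x, y) {
  ng_assert(length(x) >= 1 && length(y) >= 1, "both samples must be nonempty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
         n_x = length(x), n_y = length(y))
}
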