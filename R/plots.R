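#' Signature heatmap of a pattern model
#'
#' Patterns by phenotypes, tile fill = signature value (cluster-centroid
#' embedding mass), the standard way to read which cell types make up each
#' niche pattern.
#'
#' @param object A `pattern_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pattern_model <- function(object, ...) {
  d <- tidy(object)
  d$phenotype <- factor(d$phenotype, levels = object$vocabulary$phenotype)
  d$pattern <- factor(d$pattern,
                      levels = rev(rownames(object$signatures)))
  ggplot(d, aes(x = .data$phenotype, y = .data$pattern,
                fill = .data$signature)) +
    geom_tile() +
    scale_fill_viridis_c(name = "signature") +
    labs(x = "cell phenotype", y = "pattern") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Population-graph layout colored by subgroup
#'
#' @param object A `population_graph` with communities detected.
#' @param seed Layout seed; default 1.
#' @param ... Unused.
#' @return A ggplot of the 2D force-directed layout.
#' @export
autoplot.population_graph <- function(object, seed = 1, ...) {
  coords <- layout_population(object, seed = seed, dim = 2)
  coords$subgroup <- if (!is.null(object$subgroup))
    factor(object$subgroup) else factor(1)
  seg <- tibble(
    x = coords$x[object$edges$from], y = coords$y[object$edges$from],
    xend = coords$x[object$edges$to], yend = coords$y[object$edges$to],
    weight = object$edges$weight)
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, alpha = .data$weight),
                 color = "grey60", show.legend = FALSE) +
    geom_point(data = coords,
               aes(x = .data$x, y = .data$y, color = .data$subgroup),
               size = 2) +
    labs(color = "subgroup") +
    theme_void()
}

#' Kaplan-Meier curves per subgroup
#'
#' Step curves of the product-limit survival estimates returned by
#' [km_estimate()].
#'
#' @param km A [km_estimate()] tibble.
#' @return A ggplot.
#' @export
plot_km <- function(km) {
  ng_assert(all(c("group", "time", "estimate") %in% names(km)),
            "expected a km_estimate() tibble")
  ggplot(km, aes(x = .data$time, y = .data$estimate,
                 color = factor(.data$group))) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (months)", y = "survival probability",
         color = "subgroup") +
    theme_minimal()
}

#' Hazard-ratio forest plot per subgroup
#'
#' @param cox A [cox_subgroup_hr()] tibble.
#' @return A ggplot with point estimates and 95% CIs on a log scale.
#' @export
plot_hazard_ratios <- function(cox) {
  ng_assert(all(c("subgroup", "hr", "conf.low", "conf.high") %in% names(cox)),
            "expected a cox_subgroup_hr() tibble")
  d <- cox[!is.na(cox$hr), ]
  ggplot(d, aes(x = .data$hr, y = factor(.data$subgroup))) +
    geom_vline(xintercept = 1, linetype = 2, color = "grey50") +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$conf.low, xmax = .data$conf.high),
                   height = 0.2) +
    scale_x_log10() +
    labs(x = "hazard ratio (vs rest)", y = "subgroup") +
    theme_minimal()
}

#' Spatial map of one patient's cells
#'
#' @param cells Cell table restricted to one patient.
#' @param color Column to color by; default `"phenotype"`.
#' @return A ggplot, one facet per image.
#' @export
plot_cells <- function(cells, color = "phenotype") {
  cells <- validate_cell_table(cells)
  ggplot(cells, aes(x = .data$x, y = .data$y,
                    color = factor(.data[[color]]))) +
    geom_point(size = 0.8) +
    coord_equal() +
    facet_wrap(~image_id) +
    labs(color = color, x = "x (μm)", y = "y (μm)") +
    theme_minimal()
}

#' Overview plot of a fitted model
#'
#' @param object A `softwl_fit`.
#' @param ... Unused.
#' @return The population-graph plot colored by subgroup.
#' @export
autoplot.softwl_fit <- function(object, ...) {
  autoplot(object$population, seed = object$config$random_seed)
}
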