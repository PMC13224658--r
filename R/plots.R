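# ggplot2 views of the main result types.

#' Coefficient forest plot of a model average
#'
#' @param object A `pollenscape_avg`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pollenscape_avg <- function(object, ...) {
  d <- filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term,
                                  xmin = .data$ci_low, xmax = .data$ci_high,
                                  colour = .data$component)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "averaged standardized coefficient (95% CI)", y = NULL,
                  colour = "component") +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a single zero-inflated fit
#'
#' @param object A `pollenscape_ziglmm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pollenscape_ziglmm <- function(object, ...) {
  d <- filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term,
                                  xmin = .data$estimate - 1.96 * .data$se,
                                  xmax = .data$estimate + 1.96 * .data$se,
                                  colour = .data$component)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "coefficient (Wald 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Monoclonality by shoot-cluster size class
#'
#' @param object A `clonality_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clonality_report <- function(object, ...) {
  d <- object$by_size_class
  d$size_class <- factor(d$size_class, levels = c("<5", "5-20", ">20"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size_class, y = .data$prop_monoclonal)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::geom_hline(yintercept = object$overall_monoclonal_fraction,
                        linetype = 2, colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "shoot-cluster size class (shoots)",
                  y = "proportion of monoclonal clusters") +
    ggplot2::theme_minimal()
}

#' Distribution of per-receptor pollen-flow measures
#'
#' @param summaries Output of [receptor_summaries()].
#' @param measure `"pf_within"`, `"immigration_rate"` or `"a_r"`.
#' @return A ggplot.
#' @export
plot_receptor_measure <- function(summaries,
                                  measure = c("pf_within", "immigration_rate", "a_r")) {
  measure <- match.arg(measure)
  d <- filter(summaries, !is.na(.data[[measure]]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$patch_id, y = .data[[measure]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6,
                         ggplot2::aes(colour = .data$patch_id), show.legend = FALSE) +
    ggplot2::labs(x = "forest patch", y = measure) +
    ggplot2::theme_minimal()
}

#' Map of a synthetic study
#'
#' Patch outlines, shoot clusters and receptor positions.
#'
#' @param study A `sim_study`.
#' @return A ggplot.
#' @export
plot_study_map <- function(study) {
  rings <- bind_rows(lapply(seq_len(nrow(study$landscape$patches)), function(i) {
    r <- .close_ring(study$landscape$patches$geometry[[i]])
    tibble(patch_id = study$landscape$patches$patch_id[i], x = r[, 1], y = r[, 2])
  }))
  rec <- filter(study$genotypes, .data$role == "receptor")
  ggplot2::ggplot() +
    ggplot2::geom_path(data = rings,
                       ggplot2::aes(x = .data$x, y = .data$y, group = .data$patch_id),
                       colour = "darkgreen") +
    ggplot2::geom_point(data = study$clusters,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 0.3,
                        colour = "grey60") +
    ggplot2::geom_point(data = rec, ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "orange", size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
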