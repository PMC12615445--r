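# ggplot2 visualizations of the main result types.

#' Plot a Kaplan-Meier curve
#'
#' Step curves per stratum with censoring ticks, drawn from the
#' product-limit table.
#'
#' @param object A [km_estimate()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(stratum = unique(object$stratum), time = 0, survival = 1),
    as_tibble(object)[c("stratum", "time", "survival")]
  ) %>% arrange(.data$stratum, .data$time)
  cens <- as_tibble(object) %>% filter(.data$n_censor > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Composite scores by study group
#'
#' Box-and-jitter plot of a score column across the HD / pre-treatment /
#' post-treatment groups.
#'
#' @param scores A [score_cohort()] table (needs a `group` column).
#' @param score Score column (tidy-eval; default `exhaustion_global`).
#' @return A ggplot.
#' @export
plot_score_groups <- function(scores, score = exhaustion_global) {
  ggplot2::ggplot(scores, ggplot2::aes(.data$group, {{ score }},
                                       colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Dysbiosis vs exhaustion scatter
#'
#' Scatter of the dysbiosis score against the global exhaustion score,
#' coloured by group, with the Spearman correlation in the subtitle.
#'
#' @param scores A [score_cohort()] table.
#' @return A ggplot.
#' @export
plot_score_correlation <- function(scores) {
  sp <- spearman_correlation(scores$dysbiosis_score,
                             scores$exhaustion_global)
  ggplot2::ggplot(scores, ggplot2::aes(.data$dysbiosis_score,
                                       .data$exhaustion_global)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$group),
                         width = 0.15, height = 0.15, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.5) +
    ggplot2::labs(
      x = "Dysbiosis score", y = "Global NK exhaustion score",
      subtitle = sprintf("Spearman rho = %.2f (p = %.2g, n = %d)",
                         sp$rho, sp$p_value, sp$n)
    ) +
    ggplot2::theme_minimal()
}
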