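# broom-style tidiers for the package's fitted objects.

#' Tidy a risk model
#'
#' One row per term (intercept first): coefficient, odds ratio, and for
#' refit models the Wald standard error, p-value and 95% CI on the
#' odds-ratio scale.
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.risk_model <- function(x, ...) {
  terms <- c("(Intercept)", names(x$coefficients))
  est <- c(x$intercept, unname(x$coefficients))
  out <- tibble(
    term = terms,
    estimate = est,
    odds_ratio = exp(est)
  )
  if (!is.null(x$std_errors)) {
    se <- unname(x$std_errors[terms])
    out$std_error <- se
    out$p_value <- unname(x$p_values[terms])
    out$or_conf_low <- exp(est - 1.96 * se)
    out$or_conf_high <- exp(est + 1.96 * se)
  }
  out
}

#' Glance at a risk model
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A one-row tibble: name, provenance, nobs, deviance,
#'   convergence and separation flags.
#' @export
glance.risk_model <- function(x, ...) {
  tibble(
    name = x$name, provenance = x$provenance, nobs = x$nobs,
    deviance = x$deviance, converged = x$converged,
    separation = x$separation
  )
}

#' Tidy a log-rank result
#'
#' Per-stratum observed and expected event counts.
#' @param x A [logrank_test()] result.
#' @param ... Unused.
#' @return A tibble with `stratum`, `observed`, `expected`.
#' @export
tidy.gutnk_logrank <- function(x, ...) {
  attr(x, "counts")
}

#' Glance at a log-rank result
#' @param x A [logrank_test()] result.
#' @param ... Unused.
#' @return The one-row summary tibble (chi-square, p, HR and CI).
#' @export
glance.gutnk_logrank <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Tidy a Kaplan-Meier curve
#' @param x A [km_estimate()] result.
#' @param ... Unused.
#' @return The step-function table as a plain tibble.
#' @export
tidy.km_curve <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Tidy a healthy-donor reference
#' @param x A [fit_reference()] object.
#' @param ... Unused.
#' @return Per-feature mean, SD and n (reference values dropped).
#' @export
tidy.gutnk_ref <- function(x, ...) {
  out <- as_tibble(x)[c("feature", "mean", "sd", "n")]
  class(out) <- class(tibble())
  out
}
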