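#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling and a two-sided
#' p-value: the exact null distribution of the rank statistic for n <= 10
#' (tie-free case), the t-approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @examples
#' spearman_correlation(c(1, 2, 3), c(2, 1, 3))
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) abort("inputs contain NA")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("rank correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = length(x) <= 10)
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# --- risk models ----------------------------------------------------------

new_risk_model <- function(name, intercept, coefficients, provenance,
                           std_errors = NULL, p_values = NULL,
                           nobs = NA_integer_, deviance = NA_real_,
                           converged = TRUE, separation = FALSE) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), !is.null(names(coefficients)),
            !anyDuplicated(names(coefficients)))
  structure(
    list(name = name, intercept = intercept, coefficients = coefficients,
         provenance = provenance, std_errors = std_errors,
         p_values = p_values, nobs = nobs, deviance = deviance,
         converged = converged, separation = separation),
    class = "risk_model"
  )
}

#' Fixed-coefficient risk models
#'
#' The two published logistic risk equations, shipped as immutable
#' fixtures with coefficients exactly as printed.
#'
#' `cc_risk_model()` predicts cervical cancer (vs healthy donor):
#' `logit(P) = -3.3919 + 0.5938 * pd1_cd56bright + 2.6358 *
#' escherichia_ruminococcus` where `pd1_cd56bright` is percent PD-1+
#' CD56bright NK cells (0-100 scale) and `escherichia_ruminococcus` the
#' CLR log-ratio.
#'
#' `mortality_risk_model()` predicts 15-month mortality among
#' pre-treatment patients: `logit(P) = -105.640 + 0.208 *
#' tigit_tim3_cd56bright + 1.058 * cd56dim_freq` (percent
#' TIGIT+TIM-3+ CD56bright NK cells and percent CD56dim NK cells).
#'
#' @return A `risk_model` object.
#' @name printed_models
NULL

#' @rdname printed_models
#' @export
cc_risk_model <- function() {
  new_risk_model(
    name = "cc_risk_2var",
    intercept = -3.3919,
    coefficients = c(pd1_cd56bright = 0.5938,
                     escherichia_ruminococcus = 2.6358),
    provenance = "printed"
  )
}

#' @rdname printed_models
#' @export
mortality_risk_model <- function() {
  new_risk_model(
    name = "mortality_2var",
    intercept = -105.640,
    coefficients = c(tigit_tim3_cd56bright = 0.208,
                     cd56dim_freq = 1.058),
    provenance = "printed"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model '%s' (%s)>\n", x$name, x$provenance))
  cat(sprintf("  logit(P) = %.4f", x$intercept))
  for (f in names(x$coefficients)) {
    cat(sprintf(" + %.4f*%s", x$coefficients[[f]], f))
  }
  cat("\n")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (x$separation) cat("  WARNING: (quasi-)separation detected\n")
  invisible(x)
}

#' Evaluate a logistic risk model on new data
#'
#' Computes the linear predictor and the event probability
#' `P = 1 / (1 + exp(-(b0 + sum b_j x_j)))` for each row.
#'
#' @param data Data frame containing every model feature as a column, or a
#'   named numeric vector for a single subject.
#' @param model A `risk_model`.
#' @return `data` as a tibble with added columns `.logit` and `.prob`.
#' @examples
#' evaluate_risk(c(pd1_cd56bright = 0, escherichia_ruminococcus = 0),
#'               cc_risk_model())
#' @export
evaluate_risk <- function(data, model) {
  stopifnot(inherits(model, "risk_model"))
  if (is.numeric(data) && !is.null(names(data))) {
    data <- as_tibble(as.list(data))
  }
  feats <- names(model$coefficients)
  missing <- setdiff(feats, names(data))
  if (length(missing) > 0) {
    abort(sprintf("missing model feature(s): %s", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(as.data.frame(data)[feats])
  eta <- model$intercept + drop(x %*% model$coefficients[feats])
  out <- as_tibble(data)
  out$.logit <- eta
  out$.prob <- plogis(eta)
  out
}

#' Odds ratio from a logistic coefficient
#'
#' @param beta Coefficient(s) on the log-odds scale.
#' @return `exp(beta)`.
#' @export
odds_ratio_from_coef <- function(beta) exp(beta)

#' Refit a logistic risk model by maximum likelihood
#'
#' Fits `labels ~ features` with [stats::glm()] (binomial, logit link) and
#' wraps the result as a `risk_model` with Wald standard errors. Perfect or
#' quasi-perfect separation is detected (non-convergence or exploding
#' coefficients) and flagged rather than silently reported.
#'
#' @param data Data frame of predictor columns.
#' @param labels Binary outcome (0/1 or logical), length `nrow(data)`.
#' @param features Character vector of predictor columns (default: all).
#' @param name Model name for the fixture.
#' @return A `risk_model` with `provenance = "refit"`.
#' @export
fit_logistic <- function(data, labels, features = NULL,
                         name = "refit_model") {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("`labels` must be binary 0/1")
  if (sum(labels == 0) < 2 || sum(labels == 1) < 2) {
    abort("need at least 2 observations of each class")
  }
  features <- features %||% names(data)
  if (any(vapply(data[features], function(v) sd(v) == 0, logical(1)))) {
    abort("constant feature supplied to fit_logistic")
  }
  df <- as.data.frame(data[features])
  df$.y <- labels
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = binomial())
  )
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  # complete/quasi-complete separation: perfect fit or exploding coefficients
  separation <- !fit$converged || fit$deviance < 1e-6 ||
    any(abs(cf) > 15 & se > 100)
  z <- cf / se
  p <- 2 * pnorm(-abs(z))
  new_risk_model(
    name = name,
    intercept = unname(cf[1]),
    coefficients = setNames(cf[-1], features),
    provenance = "refit",
    std_errors = setNames(se, names(cf)),
    p_values = setNames(p, names(cf)),
    nobs = nrow(df),
    deviance = fit$deviance,
    converged = fit$converged,
    separation = separation
  )
}

# --- ROC utilities --------------------------------------------------------

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("`labels` must be binary 0/1")
  if (length(unique(labels)) < 2) abort("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' The probability that a random positive outranks a random negative,
#' with ties counted 1/2 (rank-sum formulation).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary outcome.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) abort("length mismatch")
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Youden-optimal ROC cutoff
#'
#' Scans candidate thresholds at the midpoints between adjacent distinct
#' scores (plus open extremes) and returns the cutoff maximizing Youden's
#' J = sensitivity + specificity - 1, classifying `score > cutoff` as
#' positive. Ties on J resolve to the smallest cutoff. An
#' anti-informative marker (max J <= 0) is flagged via the `informative`
#' column.
#'
#' @param scores Numeric marker values.
#' @param labels Binary outcome.
#' @return A one-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`, `informative`.
#' @examples
#' youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) abort("length mismatch")
  s <- sort(unique(scores))
  cand <- if (length(s) == 1) s else (s[-1] + s[-length(s)]) / 2
  cand <- c(min(s) - 1, cand)
  stats <- vapply(cand, function(ct) {
    pos <- scores > ct
    sens <- sum(pos & labels == 1) / sum(labels == 1)
    spec <- sum(!pos & labels == 0) / sum(labels == 0)
    c(sens, spec)
  }, numeric(2))
  j <- stats[1, ] + stats[2, ] - 1
  best <- which.max(j)
  tibble(
    cutoff = cand[best],
    sensitivity = stats[1, best],
    specificity = stats[2, best],
    youden_j = j[best],
    informative = j[best] > 0
  )
}
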