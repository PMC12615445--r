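#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function S(t) = prod_(t_i <= t) (1 - d_i / n_i)
#' over distinct event times (via [survival::survfit()]). Subjects flagged
#' `lost_to_followup` are dropped before estimation.
#'
#' @param records Data frame with columns `time_months` (> 0), `event`
#'   (1 = death, 0 = censored), optionally `stratum` and
#'   `lost_to_followup`.
#' @param stratum Optional column name to stratify on (default: a
#'   `stratum` column if present, else a single pooled curve).
#' @return A `km_curve` tibble: `stratum`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
km_estimate <- function(records, stratum = NULL) {
  if (nrow(records) == 0) abort("no survival records supplied")
  stopifnot(all(c("time_months", "event") %in% names(records)))
  if (any(records$time_months <= 0)) abort("survival times must be > 0")
  if ("lost_to_followup" %in% names(records)) {
    records <- records[!records$lost_to_followup, , drop = FALSE]
    if (nrow(records) == 0) abort("all records flagged lost to follow-up")
  }
  stratum <- stratum %||% (if ("stratum" %in% names(records)) "stratum" else NULL)
  if (is.null(stratum)) {
    records$.stratum <- "all"
  } else {
    records$.stratum <- as.character(records[[stratum]])
  }
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ .stratum,
    data = records
  )
  smry <- summary(fit, censored = TRUE)
  strata_lab <- if (is.null(smry$strata)) {
    rep(unique(records$.stratum), length(smry$time))
  } else {
    sub(".*=", "", as.character(smry$strata))
  }
  out <- tibble(
    stratum = strata_lab,
    time = smry$time,
    n_risk = smry$n.risk,
    n_event = smry$n.event,
    n_censor = smry$n.censor,
    survival = smry$surv
  )
  structure(out, class = c("km_curve", class(out)))
}

#' Median survival from a KM curve
#'
#' The smallest time at which the estimated survival drops to 0.5 or
#' below; `NA` if the curve never reaches 0.5 (flagged undefined).
#'
#' @param curve A [km_estimate()] result.
#' @return A tibble with one row per stratum: `stratum`,
#'   `median_months` (`NA` when undefined).
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  curve %>%
    group_by(.data$stratum) %>%
    summarise(
      median_months = {
        hit <- .data$time[.data$survival <= 0.5]
        if (length(hit) == 0) NA_real_ else min(hit)
      },
      .groups = "drop"
    )
}

#' Log-rank test and hazard ratio between two strata
#'
#' Standard log-rank test (via [survival::survdiff()]) comparing the two
#' strata of `records`, with the hazard ratio reported either as the
#' ratio of observed/expected event counts (`"oe"`, the log-rank HR) or
#' as the Mantel-Haenszel estimate `exp((O1 - E1) / V)`. The HR compares
#' the first stratum level against the second; 95% CIs use the log-scale
#' normal approximation (`se = sqrt(1/E1 + 1/E2)` for O/E,
#' `se = 1/sqrt(V)` for Mantel-Haenszel). Lost-to-follow-up records are
#' excluded first.
#'
#' @param records Data frame with `time_months`, `event`, and a stratum
#'   column with exactly two levels.
#' @param stratum Stratum column name (default `"stratum"`).
#' @param hr_method `"oe"` or `"mantel_haenszel"`.
#' @return A one-row tibble: `chi_square`, `p_value`, `hazard_ratio`,
#'   `hr_lower`, `hr_upper`, `hr_method`, `n`, `events`, plus the
#'   per-stratum observed/expected counts as attribute `"counts"`.
#' @export
logrank_test <- function(records, stratum = "stratum",
                         hr_method = c("oe", "mantel_haenszel")) {
  hr_method <- arg_match(hr_method)
  stopifnot(all(c("time_months", "event", stratum) %in% names(records)))
  if ("lost_to_followup" %in% names(records)) {
    records <- records[!records$lost_to_followup, , drop = FALSE]
  }
  g <- records[[stratum]]
  g <- if (is.factor(g)) droplevels(g) else factor(g)
  if (nlevels(g) != 2) abort("log-rank test needs exactly two strata")
  if (any(table(g) == 0)) abort("each stratum must be nonempty")
  if (sum(records$event) == 0) abort("no events observed; log-rank test undefined")
  records$.g <- g
  fit <- survival::survdiff(
    survival::Surv(time_months, event) ~ .g, data = records
  )
  obs <- fit$obs
  expd <- fit$exp
  v <- fit$var[1, 1]
  chi <- fit$chisq
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  if (hr_method == "oe") {
    hr <- (obs[1] / expd[1]) / (obs[2] / expd[2])
    se <- sqrt(1 / expd[1] + 1 / expd[2])
  } else {
    hr <- exp((obs[1] - expd[1]) / v)
    se <- 1 / sqrt(v)
  }
  out <- tibble(
    chi_square = chi, p_value = p,
    hazard_ratio = unname(hr),
    hr_lower = unname(exp(log(hr) - 1.96 * se)),
    hr_upper = unname(exp(log(hr) + 1.96 * se)),
    hr_method = hr_method,
    n = nrow(records), events = sum(records$event)
  )
  attr(out, "counts") <- tibble(
    stratum = levels(g), observed = as.numeric(obs),
    expected = as.numeric(expd)
  )
  class(out) <- c("gutnk_logrank", class(out))
  out
}

#' Stratify subjects by the Youden-optimal cutoff of a marker
#'
#' Derives the cutoff from the ROC of `marker` against the binary
#' outcome `status` ([youden_cutoff()]), then labels subjects with marker
#' value above the cutoff `"high"` and the rest `"low"`.
#'
#' @param data Data frame of aligned subjects.
#' @param marker Column with the marker values (tidy-eval).
#' @param status Column with the binary outcome used to place the cutoff
#'   (tidy-eval; typically the event flag).
#' @param name Name of the added stratum column (default `"stratum"`).
#' @return `data` with the stratum column added (factor, levels
#'   `high`/`low`); the cutoff tibble is attached as attribute
#'   `"cutoff"`.
#' @export
stratify_by_cutoff <- function(data, marker, status, name = "stratum") {
  values <- dplyr::pull(data, {{ marker }})
  labels <- dplyr::pull(data, {{ status }})
  cut <- youden_cutoff(values, labels)
  out <- as_tibble(data)
  out[[name]] <- factor(ifelse(values > cut$cutoff, "high", "low"),
                        levels = c("high", "low"))
  attr(out, "cutoff") <- cut
  out
}

#' Concordant joint strata for two markers
#'
#' Combines two high/low stratifications, keeping only subjects
#' concordant on both markers (`high/high` or `low/low`); discordant
#' subjects get `NA` and are excluded from the extreme-category
#' comparison.
#'
#' @param data Data frame with two stratum columns.
#' @param stratum1,stratum2 Column names of the two stratifications.
#' @param name Name of the added joint column (default `"stratum_joint"`).
#' @return `data` with the joint column added (factor, levels
#'   `high/high`, `low/low`; `NA` = excluded).
#' @export
combined_strata <- function(data, stratum1, stratum2,
                            name = "stratum_joint") {
  s1 <- as.character(data[[stratum1]])
  s2 <- as.character(data[[stratum2]])
  joint <- dplyr::case_when(
    s1 == "high" & s2 == "high" ~ "high/high",
    s1 == "low" & s2 == "low" ~ "low/low",
    TRUE ~ NA_character_
  )
  if (all(is.na(joint))) abort("no concordant subjects; combined strata empty")
  out <- as_tibble(data)
  out[[name]] <- factor(joint, levels = c("high/high", "low/low"))
  out
}
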