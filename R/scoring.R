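#' Healthy-donor reference distribution
#'
#' Summarises healthy-donor (HD) observations per feature: mean, SD
#' (denominator n-1), and the sorted raw values used for empirical
#' percentile thresholds. Z-scores and percentile bins for every subject
#' are computed against this reference.
#'
#' @param data Long data frame of HD observations.
#' @param feature,value Columns holding the feature name and numeric value
#'   (tidy-eval; defaults `feature` and `value`).
#' @return A `gutnk_ref` object (tibble with one row per feature and a
#'   list-column of sorted reference values).
#' @examples
#' hd <- tibble::tibble(feature = "PD-1", value = c(8, 10, 12))
#' fit_reference(hd)
#' @export
fit_reference <- function(data, feature = feature, value = value) {
  feats <- dplyr::pull(data, {{ feature }})
  vals <- dplyr::pull(data, {{ value }})
  if (any(is.na(vals))) abort("reference values contain NA")
  ref <- tibble(feature = as.character(feats), value = as.numeric(vals)) %>%
    group_by(feature) %>%
    summarise(
      mean = mean(value),
      sd = sd(value),
      n = n(),
      values = list(sort(value)),
      .groups = "drop"
    )
  if (any(ref$n < 2)) {
    abort(sprintf(
      "need >= 2 reference observations per feature; too few for: %s",
      paste(ref$feature[ref$n < 2], collapse = ", ")
    ))
  }
  if (any(ref$sd == 0)) {
    abort(sprintf(
      "zero reference variance for: %s. Exclude the feature (or jitter the reference); a degenerate SD cannot anchor Z-scores.",
      paste(ref$feature[ref$sd == 0], collapse = ", ")
    ))
  }
  structure(ref, class = c("gutnk_ref", class(ref)))
}

ref_row <- function(ref, feature) {
  i <- match(feature, ref$feature)
  if (any(is.na(i))) {
    abort(sprintf(
      "feature not in reference: %s",
      paste(unique(feature[is.na(i)]), collapse = ", ")
    ))
  }
  i
}

#' Z-score against the healthy-donor reference
#'
#' @param x Numeric values.
#' @param ref A [fit_reference()] object.
#' @param feature Feature name (length 1 or recycled against `x`).
#' @return Numeric vector `(x - mean) / sd`.
#' @export
z_score <- function(x, ref, feature) {
  i <- ref_row(ref, feature)
  (x - ref$mean[i]) / ref$sd[i]
}

#' Percentile bin rule
#'
#' Defines how a Z-score is classified into an ordinal score 1/2/3 against
#' the empirical reference distribution. Under `one_sided`, the Z-score is
#' compared to the reference Z-values at the `cut_lo` and `cut_hi`
#' percentiles (higher = worse). Under `two_sided`, |Z| is compared to the
#' percentiles of the reference |Z| distribution, so departures in either
#' direction raise the score.
#'
#' @param mode `"one_sided"` or `"two_sided"`.
#' @param cut_lo,cut_hi Percentile cuts in (0, 100), `cut_lo < cut_hi`.
#'   Defaults 66.7 and 90: the top tercile of the reference earns 2, the
#'   top decile 3.
#' @return A `bin_rule` list.
#' @export
bin_rule <- function(mode = c("one_sided", "two_sided"),
                     cut_lo = 66.7, cut_hi = 90) {
  mode <- arg_match(mode)
  if (!(cut_lo > 0 && cut_hi < 100 && cut_lo < cut_hi)) {
    abort("need 0 < cut_lo < cut_hi < 100")
  }
  structure(list(mode = mode, cut_lo = cut_lo, cut_hi = cut_hi),
            class = "bin_rule")
}

#' Classify Z-scores into ordinal bins 1-3
#'
#' Percentile thresholds are linearly interpolated on the empirical
#' reference values ([stats::quantile()] type 7). A value at or below the
#' low threshold scores 1, between the thresholds 2, above the high
#' threshold 3.
#'
#' @param z Numeric Z-scores (from [z_score()]).
#' @param ref A [fit_reference()] object.
#' @param feature Feature name.
#' @param rule A [bin_rule()].
#' @return Integer vector of bins in `{1, 2, 3}`.
#' @export
bin_score <- function(z, ref, feature, rule = bin_rule()) {
  stopifnot(inherits(rule, "bin_rule"))
  i <- ref_row(ref, feature)
  ref_z <- (ref$values[[i]] - ref$mean[i]) / ref$sd[i]
  if (rule$mode == "two_sided") {
    ref_z <- abs(ref_z)
    z <- abs(z)
  }
  q <- quantile(ref_z, probs = c(rule$cut_lo, rule$cut_hi) / 100,
                names = FALSE, type = 7)
  as.integer(1L + (z > q[1]) + (z > q[2]))
}

#' Default checkpoint marker set
#'
#' The six inhibitory receptors scored on each NK subset.
#' @return Character vector.
#' @export
nk_markers <- function() {
  c("PD-1", "LAG-3", "BTLA", "TIM-3", "TIGIT", "NKG2A")
}

#' Per-subset exhaustion score
#'
#' Sum of the six marker bins for one NK subset; bounded in
#' `[6, 18]` for the default marker set.
#'
#' @param bins Named integer vector of bins (names = markers).
#' @param markers Required marker set.
#' @return Integer sum.
#' @export
subset_exhaustion_score <- function(bins, markers = nk_markers()) {
  missing <- setdiff(markers, names(bins))
  if (length(missing) > 0) {
    abort(sprintf("missing marker bins: %s", paste(missing, collapse = ", ")))
  }
  b <- bins[markers]
  if (any(!b %in% 1:3)) abort("bins must be integers in 1..3")
  sum(b)
}

#' Global exhaustion score
#'
#' Mean of the CD56dim and CD56bright subset scores.
#'
#' @param s_dim,s_bright Subset scores.
#' @param n_markers Number of markers per subset (defines the valid range
#'   `[n, 3n]`).
#' @return Numeric mean.
#' @export
global_exhaustion_score <- function(s_dim, s_bright,
                                    n_markers = length(nk_markers())) {
  lo <- n_markers
  hi <- 3 * n_markers
  if (any(s_dim < lo | s_dim > hi) || any(s_bright < lo | s_bright > hi)) {
    abort(sprintf("subset scores must lie in [%d, %d]", lo, hi))
  }
  (s_dim + s_bright) / 2
}

#' Default dysbiosis taxa panel
#'
#' Genera scored in the dysbiosis composite: the taxa consistently
#' expanded (Prevotella, Escherichia-Shigella) or depleted (Ruminococcus,
#' Christensenellaceae R-7) in cervical cancer relative to healthy donors.
#' @return Character vector of genus names.
#' @export
dysbiosis_taxa <- function() {
  c("Prevotella", "Escherichia-Shigella", "Ruminococcus",
    "Christensenellaceae R-7")
}

#' Default diversity metrics entering the dysbiosis score
#' @return Character vector.
#' @export
dysbiosis_diversity_metrics <- function() {
  c("shannon", "pielou", "simpson", "strong")
}

#' Dysbiosis score for one subject
#'
#' Sum of two-sided percentile bins over the configured features
#' (alpha-diversity metrics and CLR abundances of the dysbiosis taxa
#' panel). Two-sided binning means deviation in either direction from the
#' healthy reference raises the score, since both expansions and
#' depletions mark dysbiosis. With `aggregate = "mean"` the sum is divided
#' by the number of features.
#'
#' @param features Named numeric vector of one subject's feature values.
#' @param ref A [fit_reference()] object covering every feature.
#' @param rule Binning rule, default two-sided.
#' @param aggregate `"sum"` (default, range `[k, 3k]` for k features) or
#'   `"mean"` (range `[1, 3]`).
#' @return A single numeric score.
#' @export
dysbiosis_score <- function(features, ref, rule = bin_rule("two_sided"),
                            aggregate = c("sum", "mean")) {
  aggregate <- arg_match(aggregate)
  if (is.null(names(features)) || any(names(features) == "")) {
    abort("`features` must be a fully named numeric vector")
  }
  bins <- vapply(names(features), function(f) {
    z <- z_score(features[[f]], ref, f)
    bin_score(z, ref, f, rule = rule)
  }, integer(1))
  total <- sum(bins)
  if (aggregate == "mean") total / length(bins) else total
}

# --- cohort-level scoring -------------------------------------------------

# NK panel feature key: "<marker>|<subset>".
nk_feature_key <- function(marker, subset) paste(marker, subset, sep = "|")

#' NK exhaustion scores for a cohort
#'
#' Builds the healthy-donor reference from subjects with `group == "HD"`,
#' Z-scores and bins every checkpoint marker on both NK subsets, sums the
#' bins per subset and averages the two subset scores into the global
#' exhaustion score.
#'
#' @param nk_panel Long panel: columns `subject_id`, `subset`
#'   (`CD56dim`/`CD56bright`), `marker`, `percent`.
#' @param metadata Data frame with `subject_id` and `group` (the `"HD"`
#'   rows define the reference).
#' @param markers Markers entering the score (default [nk_markers()];
#'   co-expression columns in the panel are ignored unless listed here).
#' @param rule Binning rule, default one-sided (higher expression = worse).
#' @return A tibble with `subject_id`, `score_cd56dim`, `score_cd56bright`,
#'   `exhaustion_global`; the per-feature breakdown (`subject_id`,
#'   `marker`, `subset`, `percent`, `z`, `bin`) is attached as attribute
#'   `"breakdown"`.
#' @export
score_exhaustion <- function(nk_panel, metadata, markers = nk_markers(),
                             rule = bin_rule("one_sided")) {
  stopifnot(all(c("subject_id", "subset", "marker", "percent") %in% names(nk_panel)))
  panel <- nk_panel %>%
    filter(.data$marker %in% markers) %>%
    mutate(feature = nk_feature_key(.data$marker, .data$subset))
  subsets <- c("CD56dim", "CD56bright")
  want <- as.character(outer(markers, subsets, nk_feature_key))
  hd_ids <- metadata$subject_id[metadata$group == "HD"]
  if (length(hd_ids) < 2) abort("need >= 2 HD subjects to fit the reference")
  complete <- panel %>%
    group_by(.data$subject_id) %>%
    summarise(missing = list(setdiff(want, .data$feature)), .groups = "drop")
  incomplete <- complete$subject_id[lengths(complete$missing) > 0]
  if (length(incomplete) > 0) {
    first <- incomplete[1]
    miss <- complete$missing[[match(first, complete$subject_id)]]
    abort(sprintf("subject %s is missing panel features: %s",
                  first, paste(miss, collapse = ", ")))
  }
  ref <- fit_reference(
    panel %>% filter(.data$subject_id %in% hd_ids),
    feature = .data$feature, value = .data$percent
  )
  breakdown <- panel %>%
    group_by(.data$feature) %>%
    mutate(
      z = z_score(.data$percent, ref, .data$feature[1]),
      bin = bin_score(.data$z, ref, .data$feature[1], rule = rule)
    ) %>%
    ungroup() %>%
    select("subject_id", "marker", "subset", "percent", "z", "bin")
  scores <- breakdown %>%
    group_by(.data$subject_id, .data$subset) %>%
    summarise(score = sum(.data$bin), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "subset", values_from = "score") %>%
    rename(score_cd56dim = "CD56dim", score_cd56bright = "CD56bright") %>%
    mutate(exhaustion_global = global_exhaustion_score(
      .data$score_cd56dim, .data$score_cd56bright,
      n_markers = length(markers)
    ))
  attr(scores, "breakdown") <- breakdown
  attr(scores, "reference") <- ref
  scores
}

#' Microbiota dysbiosis scores for a cohort
#'
#' Computes the configured alpha-diversity metrics and genus-level CLR
#' abundances of the dysbiosis taxa panel, fits the healthy-donor
#' reference, and sums two-sided percentile bins into a per-subject
#' dysbiosis score.
#'
#' @param taxa Wide genus count table (`subject_id` + genus columns).
#' @param metadata Data frame with `subject_id` and `group`.
#' @param taxa_panel Genus names scored via CLR (default
#'   [dysbiosis_taxa()]).
#' @param diversity_metrics Alpha-diversity columns scored (default
#'   [dysbiosis_diversity_metrics()]).
#' @param rule Binning rule, default two-sided.
#' @param pseudocount CLR pseudocount.
#' @param aggregate `"sum"` or `"mean"` over feature bins.
#' @param base Log base for Shannon/Pielou.
#' @return A tibble with `subject_id`, `dysbiosis_score`, `n_features`;
#'   breakdown attached as attribute `"breakdown"`.
#' @export
score_dysbiosis <- function(taxa, metadata,
                            taxa_panel = dysbiosis_taxa(),
                            diversity_metrics = dysbiosis_diversity_metrics(),
                            rule = bin_rule("two_sided"),
                            pseudocount = 0.5,
                            aggregate = c("sum", "mean"),
                            base = 2) {
  aggregate <- arg_match(aggregate)
  alpha <- alpha_diversity(taxa, base = base)
  bad_metric <- setdiff(diversity_metrics, setdiff(names(alpha), "subject_id"))
  if (length(bad_metric) > 0) {
    abort(sprintf("unknown diversity metric: %s", paste(bad_metric, collapse = ", ")))
  }
  clr <- clr_transform(taxa, pseudocount = pseudocount)
  feats <- setdiff(names(clr), "subject_id")
  panel_cols <- vapply(taxa_panel, resolve_alias, character(1), available = feats)
  features <- dplyr::bind_cols(
    alpha[c("subject_id", diversity_metrics)],
    clr[panel_cols]
  )
  long <- tidyr::pivot_longer(features, -"subject_id",
                              names_to = "feature", values_to = "value")
  hd_ids <- metadata$subject_id[metadata$group == "HD"]
  if (length(hd_ids) < 2) abort("need >= 2 HD subjects to fit the reference")
  ref <- fit_reference(long %>% filter(.data$subject_id %in% hd_ids))
  breakdown <- long %>%
    group_by(.data$feature) %>%
    mutate(
      z = z_score(.data$value, ref, .data$feature[1]),
      bin = bin_score(.data$z, ref, .data$feature[1], rule = rule)
    ) %>%
    ungroup()
  k <- length(unique(long$feature))
  scores <- breakdown %>%
    group_by(.data$subject_id) %>%
    summarise(
      dysbiosis_score = if (aggregate == "mean") sum(.data$bin) / k else sum(.data$bin),
      n_features = k,
      .groups = "drop"
    )
  attr(scores, "breakdown") <- breakdown
  attr(scores, "reference") <- ref
  scores
}

#' Score a whole cohort
#'
#' Convenience wrapper joining [score_exhaustion()] and [score_dysbiosis()]
#' results with the cohort metadata.
#'
#' @param cohort A [generate_cohort()] object or a list with elements
#'   `taxa`, `nk_panel`, `metadata`.
#' @param ... Passed to the two scoring functions where names match.
#' @return A tibble: metadata columns plus subset scores, global
#'   exhaustion score and dysbiosis score.
#' @export
score_cohort <- function(cohort, ...) {
  dots <- list(...)
  exh_args <- dots[intersect(names(dots), c("markers", "rule"))]
  dys_args <- dots[intersect(names(dots), c(
    "taxa_panel", "diversity_metrics", "pseudocount", "aggregate", "base"
  ))]
  exh <- do.call(score_exhaustion,
                 c(list(cohort$nk_panel, cohort$metadata), exh_args))
  dys <- do.call(score_dysbiosis,
                 c(list(cohort$taxa, cohort$metadata), dys_args))
  cohort$metadata %>%
    left_join(exh, by = "subject_id") %>%
    left_join(dys, by = "subject_id")
}
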