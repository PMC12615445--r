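# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes: log-normal genus abundances with group
# log-fold shifts, elevated checkpoint percentages in cancer groups, a
# latent per-subject severity factor coupling dysbiosis to exhaustion,
# and exponential survival censored at a fixed horizon.

#' Default genus-to-phylum taxonomy map
#'
#' Twenty gut genera spanning Firmicutes, Bacteroidota, Proteobacteria,
#' Actinobacteriota and Verrucomicrobiota, covering every taxon used by
#' the ratio panel and the dysbiosis score.
#' @return A tibble with columns `genus`, `phylum`.
#' @export
default_taxonomy <- function() {
  tibble(
    genus = c(
      "Prevotella", "Bacteroides",
      "Escherichia-Shigella", "Bilophila",
      "Faecalibacterium", "Ruminococcus", "Christensenellaceae R-7",
      "Roseburia", "Phascolarctobacterium", "Erysipelotrichaceae UCG-003",
      "Streptococcus", "Oscillibacter", "Subdoligranulum", "Anaerostipes",
      "Blautia", "Dorea", "Lachnospira",
      "Bifidobacterium", "Collinsella",
      "Akkermansia"
    ),
    phylum = c(
      "Bacteroidota", "Bacteroidota",
      "Proteobacteria", "Proteobacteria",
      rep("Firmicutes", 13),
      "Actinobacteriota", "Actinobacteriota",
      "Verrucomicrobiota"
    )
  )
}

#' Default healthy-donor genus abundance baseline
#'
#' Log-scale mean and SD of each genus's latent relative abundance in the
#' healthy-donor configuration. Means are the log of target relative
#' abundances resembling a healthy gut community dominated by Firmicutes
#' (Faecalibacterium ~15%, Bacteroides ~9%, Prevotella ~4%,
#' Escherichia-Shigella ~0.3%); the common log-SD 0.8 gives realistic
#' between-subject spread.
#' @return A tibble with columns `genus`, `log_mean`, `log_sd`.
#' @export
default_baseline <- function() {
  p <- c(
    "Prevotella" = 0.037, "Bacteroides" = 0.086,
    "Escherichia-Shigella" = 0.003, "Bilophila" = 0.002,
    "Faecalibacterium" = 0.155, "Ruminococcus" = 0.0135,
    "Christensenellaceae R-7" = 0.015, "Roseburia" = 0.023,
    "Phascolarctobacterium" = 0.008, "Erysipelotrichaceae UCG-003" = 0.005,
    "Streptococcus" = 0.005, "Oscillibacter" = 0.010,
    "Subdoligranulum" = 0.025, "Anaerostipes" = 0.0085,
    "Blautia" = 0.080, "Dorea" = 0.020, "Lachnospira" = 0.020,
    "Bifidobacterium" = 0.030, "Collinsella" = 0.010,
    "Akkermansia" = 0.0072
  )
  tibble(genus = names(p), log_mean = log(unname(p)), log_sd = 0.8)
}

#' Default group log-fold shifts on genus abundances
#'
#' Natural-log shifts applied to the latent log-abundance of a genus in a
#' cancer group, relative to healthy donors: pre-treatment disease
#' enriches Prevotella (+2.49) and Escherichia-Shigella and depletes
#' Ruminococcus and Christensenellaceae R-7; the post-radio-chemotherapy
#' state deepens the depletion and strongly enriches
#' Phascolarctobacterium.
#' @return A tibble with columns `group`, `genus`, `lfc`.
#' @export
default_effects <- function() {
  dplyr::bind_rows(
    tibble(
      group = "CC_pre",
      genus = c("Prevotella", "Escherichia-Shigella", "Ruminococcus",
                "Christensenellaceae R-7", "Bilophila", "Streptococcus",
                "Phascolarctobacterium"),
      lfc = c(2.49, 1.5, -1.2, -1.0, 1.0, 0.8, 1.0)
    ),
    tibble(
      group = "CC_post",
      genus = c("Prevotella", "Escherichia-Shigella", "Ruminococcus",
                "Christensenellaceae R-7", "Bilophila", "Streptococcus",
                "Phascolarctobacterium", "Akkermansia", "Roseburia",
                "Faecalibacterium", "Collinsella", "Oscillibacter"),
      lfc = c(1.2, 2.0, -1.8, -1.6, 1.2, 1.0, 3.0, -1.5, -0.8, -0.5,
              1.0, 1.0)
    )
  )
}

#' Default healthy-donor checkpoint baselines
#'
#' Mean and SD of percent-positive for each checkpoint on each NK subset
#' in healthy donors, including the two co-expression pairs carried as
#' plain panel features.
#' @return A tibble with columns `marker`, `subset`, `mean`, `sd`.
#' @export
default_checkpoint_baseline <- function() {
  grid <- tidyr::expand_grid(
    marker = c(nk_markers(), "TIGIT+TIM-3+", "PD-1+TIGIT+"),
    subset = c("CD56dim", "CD56bright")
  )
  means <- c(
    "PD-1|CD56dim" = 5, "PD-1|CD56bright" = 8,
    "LAG-3|CD56dim" = 4, "LAG-3|CD56bright" = 5,
    "BTLA|CD56dim" = 10, "BTLA|CD56bright" = 8,
    "TIM-3|CD56dim" = 25, "TIM-3|CD56bright" = 20,
    "TIGIT|CD56dim" = 30, "TIGIT|CD56bright" = 35,
    "NKG2A|CD56dim" = 40, "NKG2A|CD56bright" = 55,
    "TIGIT+TIM-3+|CD56dim" = 12, "TIGIT+TIM-3+|CD56bright" = 10,
    "PD-1+TIGIT+|CD56dim" = 4, "PD-1+TIGIT+|CD56bright" = 5
  )
  sds <- c(
    "PD-1|CD56dim" = 3, "PD-1|CD56bright" = 4,
    "LAG-3|CD56dim" = 2.5, "LAG-3|CD56bright" = 3,
    "BTLA|CD56dim" = 4, "BTLA|CD56bright" = 4,
    "TIM-3|CD56dim" = 8, "TIM-3|CD56bright" = 8,
    "TIGIT|CD56dim" = 10, "TIGIT|CD56bright" = 10,
    "NKG2A|CD56dim" = 10, "NKG2A|CD56bright" = 12,
    "TIGIT+TIM-3+|CD56dim" = 5, "TIGIT+TIM-3+|CD56bright" = 5,
    "PD-1+TIGIT+|CD56dim" = 2.5, "PD-1+TIGIT+|CD56bright" = 3
  )
  key <- nk_feature_key(grid$marker, grid$subset)
  grid %>% mutate(mean = unname(means[key]), sd = unname(sds[key]))
}

#' Default group shifts on checkpoint percent-positive
#'
#' Additive shifts (percentage points) applied per group, marker and
#' subset: every checkpoint is elevated in the pre-treatment cancer
#' group and further elevated after radio-chemotherapy.
#' @return A tibble with columns `group`, `marker`, `subset`, `shift`.
#' @export
default_checkpoint_effects <- function() {
  base <- default_checkpoint_baseline()[c("marker", "subset")]
  pre_shift <- c(
    "PD-1|CD56dim" = 4, "PD-1|CD56bright" = 6,
    "LAG-3|CD56dim" = 3, "LAG-3|CD56bright" = 5,
    "BTLA|CD56dim" = 4, "BTLA|CD56bright" = 2,
    "TIM-3|CD56dim" = 2, "TIM-3|CD56bright" = 6,
    "TIGIT|CD56dim" = 2, "TIGIT|CD56bright" = 3,
    "NKG2A|CD56dim" = 1, "NKG2A|CD56bright" = 1,
    "TIGIT+TIM-3+|CD56dim" = 3, "TIGIT+TIM-3+|CD56bright" = 3,
    "PD-1+TIGIT+|CD56dim" = 2, "PD-1+TIGIT+|CD56bright" = 3
  )
  post_shift <- c(
    "PD-1|CD56dim" = 8, "PD-1|CD56bright" = 5,
    "LAG-3|CD56dim" = 6, "LAG-3|CD56bright" = 6,
    "BTLA|CD56dim" = 5, "BTLA|CD56bright" = 2,
    "TIM-3|CD56dim" = 4, "TIM-3|CD56bright" = 8,
    "TIGIT|CD56dim" = 4, "TIGIT|CD56bright" = 5,
    "NKG2A|CD56dim" = 2, "NKG2A|CD56bright" = 2,
    "TIGIT+TIM-3+|CD56dim" = 6, "TIGIT+TIM-3+|CD56bright" = 6,
    "PD-1+TIGIT+|CD56dim" = 4, "PD-1+TIGIT+|CD56bright" = 5
  )
  key <- nk_feature_key(base$marker, base$subset)
  dplyr::bind_rows(
    base %>% mutate(group = "CC_pre", shift = unname(pre_shift[key])),
    base %>% mutate(group = "CC_post", shift = unname(post_shift[key]))
  ) %>% select("group", "marker", "subset", "shift")
}

#' Cohort generator configuration
#'
#' Bundles and validates every knob of the synthetic cohort: group sizes
#' (defaults 28 healthy donors, 27 pre-treatment and 22 post-treatment
#' cervical cancer patients), the genus baseline/taxonomy/effect tables,
#' checkpoint baselines and shifts, the latent severity coupling, and the
#' survival model.
#'
#' The latent severity factor is one standard-normal scalar per subject.
#' It scales the subject's expression of their group's taxa shifts
#' (`lfc * (1 + latent_coupling * severity)`), moves every checkpoint by
#' `latent_coupling * severity * checkpoint_scale` percentage points, and
#' multiplies the death hazard by `exp(survival_link * severity)`. This is
#' the minimal shared-factor mechanism producing a positive
#' dysbiosis-exhaustion correlation and a severity-linked survival signal.
#'
#' @param n_hd,n_pre,n_post Group sizes (non-negative; at least one > 0).
#' @param depth Multinomial sequencing depth per sample (default 40000
#'   denoised reads).
#' @param taxonomy,baseline,effects,checkpoint_baseline,checkpoint_effects
#'   Component tables; see the `default_*()` functions.
#' @param latent_coupling Severity coupling strength in `[0, 1]`.
#' @param checkpoint_scale Percentage points of checkpoint shift per unit
#'   of `latent_coupling * severity`.
#' @param checkpoint_noise_sd If not `NULL`, overrides the per-feature
#'   baseline SD of checkpoint noise.
#' @param survival_link Log-hazard increase per unit severity.
#' @param base_hazard Baseline death hazard per month (default 0.034,
#'   about one third cumulative mortality over the follow-up horizon).
#' @param horizon_months Administrative censoring time (default 15).
#' @param seed Integer RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_hd = 28, n_pre = 27, n_post = 22,
                          depth = 40000,
                          taxonomy = default_taxonomy(),
                          baseline = default_baseline(),
                          effects = default_effects(),
                          checkpoint_baseline = default_checkpoint_baseline(),
                          checkpoint_effects = default_checkpoint_effects(),
                          latent_coupling = 0.6,
                          checkpoint_scale = 5,
                          checkpoint_noise_sd = NULL,
                          survival_link = 0.7,
                          base_hazard = 0.034,
                          horizon_months = 15,
                          seed = 1L) {
  sizes <- c(n_hd = n_hd, n_pre = n_pre, n_post = n_post)
  if (any(sizes < 0) || any(sizes != floor(sizes))) {
    abort("group sizes must be non-negative integers")
  }
  if (sum(sizes) < 1) abort("at least one subject is required")
  if (latent_coupling < 0 || latent_coupling > 1) {
    abort("`latent_coupling` must be in [0, 1]")
  }
  if (horizon_months <= 0) abort("`horizon_months` must be > 0")
  if (depth < 1) abort("`depth` must be a positive count")
  unknown <- setdiff(effects$genus, baseline$genus)
  if (length(unknown) > 0) {
    abort(sprintf("effect_map references unknown genus: %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  if (!setequal(taxonomy$genus, baseline$genus)) {
    abort("taxonomy and baseline must cover the same genera")
  }
  structure(
    list(
      n_hd = n_hd, n_pre = n_pre, n_post = n_post, depth = depth,
      taxonomy = taxonomy, baseline = baseline, effects = effects,
      checkpoint_baseline = checkpoint_baseline,
      checkpoint_effects = checkpoint_effects,
      latent_coupling = latent_coupling,
      checkpoint_scale = checkpoint_scale,
      checkpoint_noise_sd = checkpoint_noise_sd,
      survival_link = survival_link, base_hazard = base_hazard,
      horizon_months = horizon_months, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [cohort_config()]: genus counts from a
#' log-normal-relative-abundance / multinomial scheme with group log-fold
#' shifts, checkpoint percent-positive values clamped to `[0, 100]`, and
#' exponential survival censored at the horizon. Deterministic given the
#' config seed.
#'
#' @param config A [cohort_config()].
#' @return A `gutnk_cohort` list with elements `taxa` (wide counts),
#'   `taxonomy`, `nk_panel` (long), `metadata` (`subject_id`, `group`,
#'   `severity`, `time_months`, `event`, `lost_to_followup`).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_hd = 5, n_pre = 5, n_post = 0,
#'                                         depth = 2000, seed = 7))
#' cohort$metadata
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- rep(c("HD", "CC_pre", "CC_post"),
                times = c(config$n_hd, config$n_pre, config$n_post))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  severity <- rnorm(n)

  # latent log abundance -> multinomial counts
  bl <- config$baseline
  genera <- bl$genus
  eff <- matrix(0, nrow = 3, ncol = length(genera),
                dimnames = list(c("HD", "CC_pre", "CC_post"), genera))
  for (i in seq_len(nrow(config$effects))) {
    eff[config$effects$group[i], config$effects$genus[i]] <-
      config$effects$lfc[i]
  }
  counts <- matrix(0L, nrow = n, ncol = length(genera),
                   dimnames = list(ids, genera))
  for (i in seq_len(n)) {
    shift <- eff[groups[i], ] * (1 + config$latent_coupling * severity[i])
    log_ab <- bl$log_mean + shift + rnorm(length(genera), 0, bl$log_sd)
    p <- exp(log_ab - max(log_ab))
    counts[i, ] <- rmultinom(1, size = config$depth, prob = p / sum(p))
  }

  # checkpoint panel
  cb <- config$checkpoint_baseline
  ce <- config$checkpoint_effects
  panel <- tidyr::expand_grid(subject_id = ids, cb) %>%
    left_join(tibble(subject_id = ids, group = groups, severity = severity),
              by = "subject_id") %>%
    left_join(ce, by = c("group", "marker", "subset")) %>%
    mutate(shift = dplyr::coalesce(.data$shift, 0))
  noise_sd <- config$checkpoint_noise_sd %||% panel$sd
  panel <- panel %>%
    mutate(
      percent = clamp(
        .data$mean + .data$shift +
          config$latent_coupling * .data$severity * config$checkpoint_scale +
          rnorm(dplyr::n(), 0, noise_sd),
        0, 100
      )
    ) %>%
    select("subject_id", "subset", "marker", "percent")

  # exponential survival with administrative censoring
  rate <- config$base_hazard * exp(config$survival_link * severity)
  t_raw <- rexp(n, rate = rate)
  event <- as.integer(t_raw <= config$horizon_months)
  time_months <- pmin(t_raw, config$horizon_months)

  metadata <- tibble(
    subject_id = ids,
    group = factor(groups, levels = c("HD", "CC_pre", "CC_post")),
    severity = severity,
    time_months = time_months,
    event = event,
    lost_to_followup = FALSE
  )
  structure(
    list(taxa = matrix_to_taxa(counts), taxonomy = config$taxonomy,
         nk_panel = panel, metadata = metadata, config = config),
    class = "gutnk_cohort"
  )
}

#' @export
print.gutnk_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat("<gutnk_cohort> ", nrow(x$metadata), " subjects (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "), ",
      ncol(x$taxa) - 1, " genera\n", sep = "")
  invisible(x)
}

#' Flag pre-treatment subjects as lost to follow-up
#'
#' Marks exactly `n_lost` randomly chosen pre-treatment subjects as lost
#' to follow-up (the flag the survival stage uses to exclude them); all
#' other subjects are untouched.
#'
#' @param cohort A `gutnk_cohort`.
#' @param n_lost Number of pre-treatment subjects to flag.
#' @param seed RNG seed for the draw.
#' @return The cohort with updated `metadata$lost_to_followup`.
#' @export
apply_loss_to_followup <- function(cohort, n_lost, seed = 1L) {
  stopifnot(inherits(cohort, "gutnk_cohort"))
  pre <- which(cohort$metadata$group == "CC_pre")
  if (n_lost < 0 || n_lost != floor(n_lost)) abort("`n_lost` must be a non-negative integer")
  if (n_lost > length(pre)) {
    abort(sprintf("n_lost (%d) exceeds pre-treatment count (%d)",
                  n_lost, length(pre)))
  }
  if (n_lost > 0) {
    set.seed(as.integer(seed))
    lost <- sample(pre, n_lost)
    cohort$metadata$lost_to_followup[lost] <- TRUE
  }
  cohort
}
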