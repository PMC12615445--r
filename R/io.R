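# Readers/writers for the package's tabular exchange formats: TSV for
# matrices and metadata, CSV for the long checkpoint panel, JSON for
# nested results. Writers prepend '# provenance:' comment lines; readers
# skip '#' comments, so round-trips are lossless.

provenance_header <- function(provenance = NULL) {
  if (is.null(provenance)) return(character(0))
  sprintf("# provenance: %s", provenance)
}

write_with_header <- function(x, path, delim, provenance = NULL) {
  readr::write_lines(provenance_header(provenance), path)
  readr::write_delim(x, path, delim = delim, append = !is.null(provenance),
                     col_names = TRUE)
  invisible(path)
}

#' Read / write a genus count table
#'
#' Wide TSV: first column `subject_id`, one integer column per genus.
#' Duplicate subjects or genera, negative or non-numeric counts are
#' rejected with the offending name.
#'
#' @param path File path.
#' @param taxa Wide count table.
#' @param provenance Optional provenance string written as a `#` comment.
#' @return `read_taxa_table()` a validated tibble; writers return the
#'   path invisibly.
#' @name taxa_io
NULL

#' @rdname taxa_io
#' @export
read_taxa_table <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (names(x)[1] != "subject_id") {
    abort("first column of a taxa table must be `subject_id`")
  }
  header <- strsplit(grep("^[^#]", readr::read_lines(path), value = TRUE)[1],
                     "\t")[[1]]
  if (anyDuplicated(header)) {
    abort(sprintf("duplicated genus column: %s",
                  paste(unique(header[duplicated(header)]), collapse = ", ")))
  }
  for (col in setdiff(names(x), "subject_id")) {
    v <- x[[col]]
    if (!is.numeric(v)) abort(sprintf("non-numeric counts in column %s", col))
    if (any(v < 0)) {
      abort(sprintf("negative count at row %d, column %s",
                    which(v < 0)[1], col))
    }
  }
  taxa_matrix(x)  # full validation (duplicate subjects etc.)
  x
}

#' @rdname taxa_io
#' @export
write_taxa_table <- function(taxa, path, provenance = NULL) {
  taxa_matrix(taxa)
  write_with_header(taxa, path, delim = "\t", provenance = provenance)
}

#' Read / write a genus-to-phylum taxonomy map (TSV)
#' @param path File path.
#' @param taxonomy Data frame with columns `genus`, `phylum`.
#' @param provenance Optional provenance comment.
#' @name taxonomy_io
NULL

#' @rdname taxonomy_io
#' @export
read_taxonomy <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("genus", "phylum") %in% names(x))) {
    abort("taxonomy file needs columns `genus` and `phylum`")
  }
  if (anyDuplicated(x$genus)) abort("duplicated genus in taxonomy map")
  x
}

#' @rdname taxonomy_io
#' @export
write_taxonomy <- function(taxonomy, path, provenance = NULL) {
  write_with_header(taxonomy, path, delim = "\t", provenance = provenance)
}

#' Read / write the NK checkpoint panel (long CSV)
#'
#' Columns `subject_id`, `subset` (`CD56dim`/`CD56bright`), `marker`,
#' `percent` (0-100). Out-of-range percentages, unknown subsets and
#' subjects with an incomplete marker grid are rejected.
#'
#' @param path File path.
#' @param panel Long panel table.
#' @param provenance Optional provenance comment.
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
read_nk_panel <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("subject_id", "subset", "marker", "percent")
  if (!all(need %in% names(x))) {
    abort(sprintf("NK panel needs columns: %s", paste(need, collapse = ", ")))
  }
  bad_subset <- setdiff(unique(x$subset), c("CD56dim", "CD56bright"))
  if (length(bad_subset) > 0) {
    abort(sprintf("unknown NK subset: %s", paste(bad_subset, collapse = ", ")))
  }
  if (any(x$percent < 0 | x$percent > 100)) {
    i <- which(x$percent < 0 | x$percent > 100)[1]
    abort(sprintf("percent out of [0,100] for subject %s, marker %s",
                  x$subject_id[i], x$marker[i]))
  }
  grid <- x %>%
    dplyr::count(.data$subject_id, .data$subset, .data$marker)
  if (any(grid$n > 1)) abort("duplicated subject/subset/marker rows in panel")
  per_subject <- x %>%
    group_by(.data$subject_id) %>%
    summarise(k = dplyr::n_distinct(paste(.data$subset, .data$marker)),
              .groups = "drop")
  if (length(unique(per_subject$k)) > 1) {
    full <- max(per_subject$k)
    bad <- per_subject$subject_id[per_subject$k < full][1]
    have <- x %>% filter(.data$subject_id == bad)
    all_feats <- unique(paste(x$subset, x$marker))
    miss <- setdiff(all_feats, paste(have$subset, have$marker))
    abort(sprintf("subject %s missing panel entries: %s",
                  bad, paste(miss, collapse = ", ")))
  }
  x
}

#' @rdname panel_io
#' @export
write_nk_panel <- function(panel, path, provenance = NULL) {
  write_with_header(panel, path, delim = ",", provenance = provenance)
}

#' Read / write subject metadata (TSV)
#'
#' Columns `subject_id`, `group` (`HD`/`CC_pre`/`CC_post`),
#' `time_months`, `event`, `lost_to_followup`.
#' @param path File path.
#' @param metadata Metadata table.
#' @param provenance Optional provenance comment.
#' @name metadata_io
NULL

#' @rdname metadata_io
#' @export
read_metadata <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("subject_id", "group", "time_months", "event", "lost_to_followup")
  if (!all(need %in% names(x))) {
    abort(sprintf("metadata needs columns: %s", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(x$group), c("HD", "CC_pre", "CC_post"))
  if (length(bad) > 0) {
    abort(sprintf("unknown group label: %s", paste(bad, collapse = ", ")))
  }
  x$group <- factor(x$group, levels = c("HD", "CC_pre", "CC_post"))
  x$lost_to_followup <- as.logical(x$lost_to_followup)
  x
}

#' @rdname metadata_io
#' @export
write_metadata <- function(metadata, path, provenance = NULL) {
  write_with_header(metadata, path, delim = "\t", provenance = provenance)
}

#' Write a cohort's four tables to a directory
#'
#' @param cohort A `gutnk_cohort`.
#' @param dir Output directory (created if needed).
#' @param provenance Optional provenance string stamped on every file.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, provenance = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_taxa_table(cohort$taxa, file.path(dir, "taxa.tsv"), provenance)
  write_taxonomy(cohort$taxonomy, file.path(dir, "taxonomy.tsv"), provenance)
  write_nk_panel(cohort$nk_panel, file.path(dir, "nk_panel.csv"), provenance)
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"), provenance)
  invisible(dir)
}

#' Read a cohort back from a directory written by [write_cohort()]
#' @param dir Directory containing `taxa.tsv`, `taxonomy.tsv`,
#'   `nk_panel.csv`, `metadata.tsv`.
#' @return A `gutnk_cohort` list.
#' @export
read_cohort <- function(dir) {
  structure(
    list(
      taxa = read_taxa_table(file.path(dir, "taxa.tsv")),
      taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
      nk_panel = read_nk_panel(file.path(dir, "nk_panel.csv")),
      metadata = read_metadata(file.path(dir, "metadata.tsv"))
    ),
    class = "gutnk_cohort"
  )
}

#' Pipeline run configuration
#'
#' @param outdir Output directory for the run.
#' @param seed Master seed (drives the cohort and the loss draw).
#' @param cohort A [cohort_config()]; its seed is overridden by `seed`.
#' @param paths Optional named list of input files (`taxa`, `taxonomy`,
#'   `panel`, `metadata`); when given, the pipeline reads them instead of
#'   simulating.
#' @param n_lost Pre-treatment subjects flagged lost to follow-up before
#'   the survival stage (default 4).
#' @param pseudocount CLR pseudocount.
#' @param rule_exhaustion,rule_dysbiosis Binning rules.
#' @param survival_markers Score/ratio columns stratified for survival
#'   (default global exhaustion score and the Proteobacteria/Firmicutes
#'   ratio).
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, seed = 1L,
                       cohort = cohort_config(),
                       paths = NULL,
                       n_lost = 4,
                       pseudocount = 0.5,
                       rule_exhaustion = bin_rule("one_sided"),
                       rule_dysbiosis = bin_rule("two_sided"),
                       survival_markers = c("exhaustion_global",
                                            "proteobacteria_firmicutes")) {
  if (!is.null(paths)) {
    need <- c("taxa", "taxonomy", "panel", "metadata")
    missing_key <- setdiff(need, names(paths))
    if (length(missing_key) > 0) {
      abort(sprintf("paths must name: %s", paste(missing_key, collapse = ", ")))
    }
    gone <- !vapply(unlist(paths[need]), file.exists, logical(1))
    if (any(gone)) {
      abort(sprintf("input file not found: %s",
                    paste(unlist(paths[need])[gone], collapse = ", ")))
    }
  }
  structure(
    list(outdir = outdir, seed = as.integer(seed), cohort = cohort,
         paths = paths, n_lost = n_lost, pseudocount = pseudocount,
         rule_exhaustion = rule_exhaustion, rule_dysbiosis = rule_dysbiosis,
         survival_markers = survival_markers),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Chains the stages end to end: simulate (or read) the cohort, flag
#' lost-to-follow-up subjects, compute composite scores and the ratio
#' panel, run the association stage (dysbiosis-exhaustion correlation,
#' printed-model odds ratios, logistic refit of cancer status with AUC),
#' and the cutoff-stratified survival stage on pre-treatment patients.
#' Writes `scores.tsv`, `assoc.json`, `survival.json` and `run_log.txt`
#' into `config$outdir`; reruns with the same config reproduce every
#' number.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with elements `scores`, `assoc`, `survival`,
#'   `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  # hash covers the scientific configuration, not the output location
  hash_cfg <- unclass(config)
  hash_cfg$outdir <- NULL
  prov <- sprintf("gutnk %s | seed=%d | config_hash=%s",
                  as.character(utils::packageVersion("gutnk")),
                  config$seed, rlang::hash(hash_cfg))

  if (is.null(config$paths)) {
    cc <- config$cohort
    cc$seed <- config$seed
    cohort <- generate_cohort(cc)
  } else {
    cohort <- structure(
      list(
        taxa = read_taxa_table(config$paths$taxa),
        taxonomy = read_taxonomy(config$paths$taxonomy),
        nk_panel = read_nk_panel(config$paths$panel),
        metadata = read_metadata(config$paths$metadata)
      ),
      class = "gutnk_cohort"
    )
  }
  cohort <- apply_loss_to_followup(cohort, config$n_lost,
                                   seed = config$seed + 1L)

  scores <- score_cohort(cohort,
                         rule = config$rule_exhaustion,
                         pseudocount = config$pseudocount)
  ratios <- ratio_panel(cohort$taxa, cohort$taxonomy,
                        pseudocount = config$pseudocount)
  scores <- left_join(scores, ratios, by = "subject_id")
  write_with_header(scores, file.path(config$outdir, "scores.tsv"),
                    delim = "\t", provenance = prov)

  # association stage
  sp <- spearman_correlation(scores$dysbiosis_score,
                             scores$exhaustion_global)
  printed <- lapply(list(cc_risk_model(), mortality_risk_model()),
                    function(m) {
                      tibble(model = m$name,
                             term = names(m$coefficients),
                             coefficient = unname(m$coefficients),
                             odds_ratio = odds_ratio_from_coef(unname(m$coefficients)))
                    })
  cc_data <- scores %>% filter(.data$group %in% c("HD", "CC_pre"))
  refit <- fit_logistic(
    cc_data[c("exhaustion_global", "escherichia_ruminococcus")],
    labels = as.integer(cc_data$group == "CC_pre"),
    name = "cc_refit_synthetic"
  )
  refit_eval <- evaluate_risk(
    cc_data[c("exhaustion_global", "escherichia_ruminococcus")], refit
  )
  assoc <- list(
    provenance = prov,
    spearman = as.list(sp),
    printed_models = dplyr::bind_rows(printed),
    refit = tidy(refit),
    refit_auc = roc_auc(refit_eval$.prob,
                        as.integer(cc_data$group == "CC_pre"))
  )
  jsonlite::write_json(assoc, file.path(config$outdir, "assoc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # survival stage: pre-treatment patients, lost-to-follow-up excluded
  pre <- scores %>%
    filter(.data$group == "CC_pre", !.data$lost_to_followup)
  surv_out <- list(provenance = prov, evaluable = nrow(pre))
  for (mk in config$survival_markers) {
    if (!mk %in% names(pre)) abort(sprintf("survival marker not found: %s", mk))
    strat <- stratify_by_cutoff(pre, !!sym(mk), .data$event)
    lr <- logrank_test(strat)
    lr_mh <- logrank_test(strat, hr_method = "mantel_haenszel")
    km <- km_estimate(strat)
    med <- median_survival(km)
    surv_out[[mk]] <- list(
      cutoff = as.list(attr(strat, "cutoff")),
      logrank = as.list(lr),
      mantel_haenszel_hr = lr_mh$hazard_ratio,
      counts = attr(lr, "counts"),
      median_survival = med,
      curve = as_tibble(km)
    )
  }
  jsonlite::write_json(surv_out, file.path(config$outdir, "survival.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  readr::write_lines(c(
    prov,
    sprintf("R %s", as.character(getRversion())),
    sprintf("stages: simulate=%s, loss=%d, score, associate, survive",
            is.null(config$paths), config$n_lost)
  ), file.path(config$outdir, "run_log.txt"))

  invisible(list(scores = scores, assoc = assoc, survival = surv_out,
                 outdir = config$outdir))
}
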