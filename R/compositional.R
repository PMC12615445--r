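#' Aggregate a genus count table to a coarser taxonomic level
#'
#' Sums counts within each phylum using a genus-to-phylum map. At
#' `level = "genus"` the table is returned unchanged.
#'
#' @param taxa Wide count table (`subject_id` + genus columns).
#' @param taxonomy Data frame with columns `genus` and `phylum`.
#' @param level `"genus"` or `"phylum"`.
#' @return A tibble in the same wide layout, columns named by the target level.
#' @export
aggregate_taxa <- function(taxa, taxonomy, level = c("genus", "phylum")) {
  level <- arg_match(level)
  m <- taxa_matrix(taxa)
  if (level == "genus") {
    return(as_tibble(taxa))
  }
  stopifnot(all(c("genus", "phylum") %in% names(taxonomy)))
  map <- setNames(
    normalize_taxon(taxonomy$phylum),
    normalize_taxon(taxonomy$genus)
  )
  genera <- normalize_taxon(colnames(m))
  missing <- setdiff(genera, names(map))
  if (length(missing) > 0) {
    abort(sprintf(
      "genus not covered by taxonomy map: %s",
      paste(missing, collapse = ", ")
    ))
  }
  phyla <- map[genera]
  agg <- t(rowsum(t(m), group = phyla))
  matrix_to_taxa(agg)
}

#' Centered log-ratio transform of a count table
#'
#' Per sample, adds `pseudocount` to every count and maps the vector to
#' `log(x_i) - mean_j log(x_j)`: real coordinates whose row sum is zero.
#' The geometric mean is taken over the full feature set of the table
#' passed in, so ratio values depend on which composition (genus- or
#' phylum-level) you transform.
#'
#' @param taxa Wide count table (`subject_id` + feature columns).
#' @param pseudocount Positive offset added to every cell before the log
#'   (default 0.5). May be 0 only if no count is zero.
#' @return A tibble in the same layout with CLR coordinates.
#' @examples
#' taxa <- tibble::tibble(subject_id = "a", g1 = 1L, g2 = 1L, g3 = 2L)
#' clr_transform(taxa, pseudocount = 0)
#' @export
clr_transform <- function(taxa, pseudocount = 0.5) {
  m <- taxa_matrix(taxa)
  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  if (pseudocount == 0 && any(m == 0)) {
    abort("zero counts present; use a positive `pseudocount`")
  }
  x <- log(m + pseudocount)
  clr <- x - rowMeans(x)
  matrix_to_taxa(clr)
}

#' Log-ratio of two features of a CLR table
#'
#' The difference of two CLR coordinates, which equals the log of the
#' (pseudocounted) abundance ratio and is invariant to the centering.
#'
#' @param clr A CLR table from [clr_transform()].
#' @param numerator,denominator Feature (column) names.
#' @return A tibble with columns `subject_id` and `ratio`.
#' @export
taxon_ratio <- function(clr, numerator, denominator) {
  feats <- setdiff(names(clr), "subject_id")
  lookup <- setNames(feats, normalize_taxon(feats))
  num <- lookup[normalize_taxon(numerator)]
  den <- lookup[normalize_taxon(denominator)]
  if (is.na(num)) abort(sprintf("feature not found in CLR table: %s", numerator))
  if (is.na(den)) abort(sprintf("feature not found in CLR table: %s", denominator))
  tibble(
    subject_id = clr$subject_id,
    ratio = clr[[num]] - clr[[den]]
  )
}

# The five ratios reported for this cohort: two phylum-level, three
# genus-level. "Escherichia" resolves to the "Escherichia-Shigella" column
# when present (both spellings occur in 16S genus tables).
ratio_panel_spec <- function() {
  tibble(
    name = c(
      "proteobacteria_firmicutes", "bacteroidota_firmicutes",
      "escherichia_ruminococcus", "prevotella_ruminococcus",
      "escherichia_erysipelotrichaceae"
    ),
    level = c("phylum", "phylum", "genus", "genus", "genus"),
    numerator = c(
      "Proteobacteria", "Bacteroidota",
      "Escherichia", "Prevotella", "Escherichia"
    ),
    denominator = c(
      "Firmicutes", "Firmicutes",
      "Ruminococcus", "Ruminococcus", "Erysipelotrichaceae UCG-003"
    )
  )
}

resolve_alias <- function(name, available) {
  norm <- normalize_taxon(available)
  if (normalize_taxon(name) %in% norm) return(name)
  if (normalize_taxon(name) == "Escherichia" &&
      "Escherichia-Shigella" %in% norm) {
    return("Escherichia-Shigella")
  }
  abort(sprintf("taxon not resolvable in table: %s", name))
}

#' Taxonomic ratio panel
#'
#' Computes the five CLR log-ratios characterizing gut dysbiosis in this
#' cohort: Proteobacteria/Firmicutes and Bacteroidota/Firmicutes at the
#' phylum level (CLR of the phylum-aggregated table), and
#' Escherichia/Ruminococcus, Prevotella/Ruminococcus and
#' Escherichia/Erysipelotrichaceae UCG-003 at the genus level.
#'
#' @param taxa Wide genus count table.
#' @param taxonomy Genus-to-phylum map (columns `genus`, `phylum`).
#' @param pseudocount Offset for [clr_transform()].
#' @return A tibble with `subject_id` and one column per ratio.
#' @export
ratio_panel <- function(taxa, taxonomy, pseudocount = 0.5) {
  spec <- ratio_panel_spec()
  clr_genus <- clr_transform(taxa, pseudocount = pseudocount)
  phylum <- aggregate_taxa(taxa, taxonomy, level = "phylum")
  clr_phylum <- clr_transform(phylum, pseudocount = pseudocount)
  out <- tibble(subject_id = taxa$subject_id)
  for (i in seq_len(nrow(spec))) {
    tab <- if (spec$level[i] == "phylum") clr_phylum else clr_genus
    feats <- setdiff(names(tab), "subject_id")
    num <- resolve_alias(spec$numerator[i], feats)
    den <- resolve_alias(spec$denominator[i], feats)
    out[[spec$name[i]]] <- taxon_ratio(tab, num, den)$ratio
  }
  out
}
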