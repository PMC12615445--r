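# Internal helpers shared across modules.

# Wide taxa table -> integer matrix with subject IDs as rownames.
taxa_matrix <- function(taxa) {
  stopifnot(is.data.frame(taxa))
  if (!"subject_id" %in% names(taxa)) {
    abort("taxa table must have a `subject_id` column")
  }
  if (anyDuplicated(taxa$subject_id)) {
    abort("duplicated subject_id in taxa table")
  }
  genera <- setdiff(names(taxa), "subject_id")
  if (anyDuplicated(genera)) {
    abort("duplicated genus column in taxa table")
  }
  m <- as.matrix(taxa[genera])
  if (!is.numeric(m)) abort("taxa counts must be numeric")
  if (any(m < 0)) abort("taxa counts must be non-negative")
  rownames(m) <- as.character(taxa$subject_id)
  m
}

matrix_to_taxa <- function(m) {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(subject_id = rownames(m)), out)
  out
}

# Collapse runs of whitespace and trim; used before taxon-name matching.
normalize_taxon <- function(x) {
  gsub("\\s+", " ", trimws(x))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_counts_vector <- function(counts, arg = "counts") {
  if (!is.numeric(counts) || length(counts) == 0) {
    abort(sprintf("`%s` must be a non-empty numeric vector", arg))
  }
  if (any(is.na(counts))) abort(sprintf("`%s` contains NA", arg))
  if (any(counts < 0)) abort(sprintf("`%s` contains negative values", arg))
  if (sum(counts) <= 0) abort(sprintf("`%s` sums to zero; diversity undefined", arg))
  invisible(counts)
}
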