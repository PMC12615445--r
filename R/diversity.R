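#' Alpha-diversity metrics for one abundance vector
#'
#' Five within-sample diversity summaries of a genus count vector:
#' Shannon entropy, Simpson diversity (1 - sum p_i^2), Pielou evenness
#' (Shannon / log richness), Simpson evenness (inverse-Simpson / richness),
#' and Strong's dominance index. Proportions `p_i` are counts divided by the
#' sample total; richness `S` counts taxa with a nonzero count.
#'
#' Strong's index is the maximal gap between the cumulative relative
#' abundance of the `i` most abundant taxa and the uniform expectation `i/S`,
#' scanned over all ranks; it is 0 for a perfectly even community and
#' approaches 1 under extreme single-taxon dominance.
#'
#' @param counts Non-negative numeric vector of counts for one sample.
#' @param base Logarithm base for Shannon and Pielou (default 2, the
#'   convention of the amplicon diversity toolchain this mirrors).
#' @return A single numeric value.
#' @examples
#' shannon(c(2, 1, 1))       # 1.5 bits
#' simpson(c(2, 1, 1))       # 0.625
#' strong_dominance(c(3, 1)) # 0.25
#' @name alpha_metrics
NULL

#' @rdname alpha_metrics
#' @export
shannon <- function(counts, base = 2) {
  check_counts_vector(counts)
  if (base <= 1) abort("`base` must be > 1")
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' @rdname alpha_metrics
#' @export
simpson <- function(counts) {
  check_counts_vector(counts)
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' @rdname alpha_metrics
#' @export
pielou_evenness <- function(counts, base = 2) {
  check_counts_vector(counts)
  s <- sum(counts > 0)
  if (s < 2) abort("Pielou evenness undefined for a single observed taxon (S = 1)")
  shannon(counts, base = base) / log(s, base = base)
}

#' @rdname alpha_metrics
#' @export
simpson_evenness <- function(counts) {
  check_counts_vector(counts)
  p <- counts / sum(counts)
  s <- sum(counts > 0)
  (1 / sum(p^2)) / s
}

#' @rdname alpha_metrics
#' @export
strong_dominance <- function(counts) {
  check_counts_vector(counts)
  x <- sort(counts[counts > 0], decreasing = TRUE)
  s <- length(x)
  n_total <- sum(x)
  b <- cumsum(x)
  max(b / n_total - seq_len(s) / s)
}

#' Alpha-diversity table for a genus count table
#'
#' Computes the five alpha-diversity metrics for every sample of a wide
#' taxa count table (one row per subject, one column per genus).
#'
#' @param taxa Data frame with a `subject_id` column and one numeric count
#'   column per genus.
#' @param base Logarithm base for Shannon and Pielou.
#' @return A tibble with columns `subject_id`, `shannon`, `simpson`,
#'   `pielou`, `simpson_evenness`, `strong`.
#' @examples
#' taxa <- tibble::tibble(subject_id = c("a", "b"), g1 = c(5L, 1L), g2 = c(5L, 9L))
#' alpha_diversity(taxa)
#' @export
alpha_diversity <- function(taxa, base = 2) {
  m <- taxa_matrix(taxa)
  tibble(
    subject_id = rownames(m),
    shannon = unname(apply(m, 1, shannon, base = base)),
    simpson = unname(apply(m, 1, simpson)),
    pielou = unname(apply(m, 1, pielou_evenness, base = base)),
    simpson_evenness = unname(apply(m, 1, simpson_evenness)),
    strong = unname(apply(m, 1, strong_dominance))
  )
}
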