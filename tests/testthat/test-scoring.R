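ref_from <- function(values, feature = "f") {
  fit_reference(tibble::tibble(feature = feature, value = values))
}

test_that("the healthy-donor reference stores mean, sample SD and sorted values", {
  ref <- ref_from(c(8, 10, 12))
  expect_equal(ref$mean, 10)
  expect_equal(ref$sd, 2)
  expect_equal(ref$values[[1]], c(8, 10, 12))
  expect_error(ref_from(5), "2 reference observations")
  expect_error(ref_from(c(4, 4, 4)), "zero reference variance")
})

test_that("reference moments converge on standard-normal draws", {
  set.seed(31)
  ref <- ref_from(rnorm(1000))
  se_mean <- 1 / sqrt(1000)
  expect_lt(abs(ref$mean), 3 * se_mean)
  expect_lt(abs(ref$sd - 1), 3 * se_mean)  # SE of SD ~ sigma/sqrt(2n) < SE of mean
})

test_that("z_score is the standardized deviation from the reference", {
  ref <- ref_from(c(8, 10, 12))
  expect_equal(z_score(10, ref, "f"), 0)
  expect_equal(z_score(14, ref, "f"), 2)
  expect_equal(z_score(7, ref, "f"), -1.5)
  expect_error(z_score(1, ref, "ghost"), "ghost")
})

test_that("percentile bins follow the cut rule in both modes", {
  set.seed(32)
  vals <- rnorm(200)
  ref <- ref_from(vals)
  # a median subject on a symmetric reference sits in bin 1
  expect_equal(bin_score(0, ref, "f", bin_rule("one_sided")), 1L)
  # beyond every reference value -> bin 3 in both modes
  big <- z_score(max(vals) + 5, ref, "f")
  expect_equal(bin_score(big, ref, "f", bin_rule("one_sided")), 3L)
  expect_equal(bin_score(big, ref, "f", bin_rule("two_sided")), 3L)
  expect_error(bin_rule(cut_lo = 90, cut_hi = 50), "cut_lo")
})

test_that("bins match brute-force percentile thresholds on 10,000 random z", {
  set.seed(33)
  vals <- rnorm(150, mean = 4, sd = 2.5)
  ref <- ref_from(vals)
  z <- rnorm(10000, sd = 2)
  for (mode in c("one_sided", "two_sided")) {
    got <- bin_score(z, ref, "f", bin_rule(mode))
    want <- vapply(z, oracle_bin, integer(1), ref_values = sort(vals),
                   ref_mean = mean(vals), ref_sd = sd(vals),
                   mode = mode, cut_lo = 66.7, cut_hi = 90)
    expect_identical(got, want)
  }
})

test_that("subset and global exhaustion scores sum and average bins within bounds", {
  bins <- setNames(c(1L, 2L, 3L, 1L, 2L, 3L), nk_markers())
  expect_equal(subset_exhaustion_score(bins), 12)
  expect_equal(subset_exhaustion_score(setNames(rep(1L, 6), nk_markers())), 6)
  expect_equal(subset_exhaustion_score(setNames(rep(3L, 6), nk_markers())), 18)
  expect_error(subset_exhaustion_score(bins[-1]), "PD-1")
  expect_equal(global_exhaustion_score(6, 18), 12)
  expect_equal(global_exhaustion_score(6, 6), 6)
  expect_equal(global_exhaustion_score(13, 14), 13.5)
  expect_error(global_exhaustion_score(5, 10), "\\[6, 18\\]")
})

test_that("dysbiosis score attains k at the reference means and 3k at extremes", {
  set.seed(34)
  feats <- c("shannon", "pielou", "clrA", "clrB")
  hd <- tidyr::expand_grid(feature = feats, i = 1:30) |>
    dplyr::mutate(value = rnorm(dplyr::n(), mean = 10, sd = 2)) |>
    dplyr::select(feature, value)
  ref <- fit_reference(hd)
  at_mean <- setNames(ref$mean[match(feats, ref$feature)], feats)
  expect_equal(dysbiosis_score(at_mean, ref), length(feats))
  extreme <- at_mean + 100
  expect_equal(dysbiosis_score(extreme, ref), 3 * length(feats))
  expect_equal(dysbiosis_score(extreme, ref, aggregate = "mean"), 3)
  expect_error(dysbiosis_score(unname(at_mean), ref), "named")
})

test_that("cohort dysbiosis scores equal a per-feature brute-force recomputation", {
  cohort <- generate_cohort(cohort_config(n_hd = 100, n_pre = 100, n_post = 0,
                                          depth = 4000, seed = 35))
  scores <- score_dysbiosis(cohort$taxa, cohort$metadata)
  # independent path: oracle alpha metrics + oracle CLR + oracle bins
  m <- as.matrix(cohort$taxa[-1])
  ids <- cohort$taxa$subject_id
  feats <- data.frame(
    subject_id = ids,
    shannon = apply(m, 1, oracle_shannon),
    pielou = apply(m, 1, oracle_pielou),
    simpson = apply(m, 1, oracle_simpson),
    strong = apply(m, 1, oracle_strong)
  )
  clr <- t(apply(m, 1, oracle_clr_row, pseudocount = 0.5))
  colnames(clr) <- colnames(m)
  for (g in c("Prevotella", "Escherichia-Shigella", "Ruminococcus",
              "Christensenellaceae R-7")) {
    feats[[g]] <- clr[, g]
  }
  hd <- cohort$metadata$subject_id[cohort$metadata$group == "HD"]
  expected <- vapply(seq_along(ids), function(i) {
    total <- 0L
    for (f in setdiff(names(feats), "subject_id")) {
      refv <- feats[[f]][feats$subject_id %in% hd]
      z <- (feats[[f]][i] - mean(refv)) / sd(refv)
      total <- total + oracle_bin(z, sort(refv), mean(refv), sd(refv),
                                  "two_sided", 66.7, 90)
    }
    as.numeric(total)
  }, numeric(1))
  expect_equal(scores$dysbiosis_score[match(ids, scores$subject_id)], expected)
  expect_true(all(scores$dysbiosis_score >= 8 & scores$dysbiosis_score <= 24))
})

test_that("raising one marker never decreases the exhaustion scores", {
  cohort <- generate_cohort(cohort_config(n_hd = 40, n_pre = 10, n_post = 0,
                                          depth = 2000, seed = 36))
  base <- score_exhaustion(cohort$nk_panel, cohort$metadata)
  target <- cohort$metadata$subject_id[cohort$metadata$group == "CC_pre"][1]
  for (delta in c(5, 20, 60)) {
    panel2 <- cohort$nk_panel
    sel <- panel2$subject_id == target & panel2$marker == "PD-1" &
      panel2$subset == "CD56dim"
    panel2$percent[sel] <- pmin(panel2$percent[sel] + delta, 100)
    up <- score_exhaustion(panel2, cohort$metadata)
    expect_gte(up$score_cd56dim[up$subject_id == target],
               base$score_cd56dim[base$subject_id == target])
    expect_gte(up$exhaustion_global[up$subject_id == target],
               base$exhaustion_global[base$subject_id == target])
  }
})

test_that("score_exhaustion reports missing panel features by subject", {
  cohort <- generate_cohort(cohort_config(n_hd = 5, n_pre = 2, n_post = 0,
                                          depth = 1000, seed = 37))
  broken <- cohort$nk_panel |>
    dplyr::filter(!(subject_id == "S006" & marker == "TIM-3" & subset == "CD56dim"))
  expect_error(score_exhaustion(broken, cohort$metadata), "S006.*TIM-3")
})
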