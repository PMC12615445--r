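# Independent naive-loop oracles. Deliberately slow and literal: every
# quantity is recomputed from its definition with explicit loops, never by
# calling the package's own code paths.

oracle_shannon <- function(counts, base = 2) {
  p <- counts / sum(counts)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi, base)
  h
}

oracle_simpson <- function(counts) {
  p <- counts / sum(counts)
  s <- 0
  for (pi in p) s <- s + pi * pi
  1 - s
}

oracle_pielou <- function(counts, base = 2) {
  s <- sum(counts > 0)
  oracle_shannon(counts, base) / log(s, base)
}

oracle_simpson_evenness <- function(counts) {
  p <- counts / sum(counts)
  s <- sum(counts > 0)
  (1 / sum(p^2)) / s
}

oracle_strong <- function(counts) {
  x <- sort(counts[counts > 0], decreasing = TRUE)
  s <- length(x)
  n <- sum(x)
  best <- -Inf
  for (i in seq_len(s)) {
    best <- max(best, sum(x[1:i]) / n - i / s)
  }
  best
}

oracle_clr_row <- function(counts, pseudocount) {
  x <- counts + pseudocount
  lx <- log(x)
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- lx[i] - mean(lx)
  out
}

# bins by explicitly computed percentile thresholds on the raw reference
oracle_bin <- function(z, ref_values, ref_mean, ref_sd, mode, cut_lo, cut_hi) {
  ref_z <- (ref_values - ref_mean) / ref_sd
  if (mode == "two_sided") {
    ref_z <- abs(ref_z)
    z <- abs(z)
  }
  thr <- stats::quantile(ref_z, c(cut_lo, cut_hi) / 100, names = FALSE)
  if (z <= thr[1]) 1L else if (z <= thr[2]) 2L else 3L
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- if (length(s) == 1) s else (s[-1] + s[-length(s)]) / 2
  cand <- c(min(s) - 1, cand)
  best_j <- -Inf
  best <- NULL
  for (ct in cand) {
    sens <- sum(scores > ct & labels == 1) / sum(labels == 1)
    spec <- sum(scores <= ct & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j) {
      best_j <- j
      best <- c(cutoff = ct, sensitivity = sens, specificity = spec)
    }
  }
  best
}

# product-limit estimate at each distinct event time
oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (k in seq_along(ev_times)) {
    t <- ev_times[k]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ev_times, survival = surv)
}

# log-rank via explicit 2x2 table at every event time; group1 = first level
oracle_logrank <- function(time, event, group) {
  lev <- levels(factor(group))
  g1 <- group == lev[1]
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    n2 <- n - n1
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + n1 * d / n
    if (n > 1) V <- V + n1 * n2 * d * (n - d) / (n^2 * (n - 1))
  }
  O <- sum(event)
  O2 <- O - O1
  E2 <- O - E1
  chi <- (O1 - E1)^2 / V
  list(O1 = O1, E1 = E1, O2 = O2, E2 = E2, V = V, chi = chi,
       hr_oe = (O1 / E1) / (O2 / E2), hr_mh = exp((O1 - E1) / V))
}

# small random fixtures ---------------------------------------------------

random_counts <- function(s_max = 12) {
  s <- sample(2:s_max, 1)
  counts <- rpois(s, lambda = sample(c(2, 10, 50), 1)) + sample(0:1, s, TRUE)
  if (sum(counts) == 0) counts[1] <- 1
  counts
}

toy_taxa <- function(n_subjects = 3, genera = c("g1", "g2", "g3", "g4")) {
  m <- matrix(sample(0:50, n_subjects * length(genera), TRUE),
              nrow = n_subjects, dimnames = list(NULL, genera))
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("s%d", seq_len(n_subjects))),
    tibble::as_tibble(m)
  )
}
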