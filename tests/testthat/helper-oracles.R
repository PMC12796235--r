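# Independent oracles: literal transcriptions of the defining formulas,
# deliberately written as plain loops with none of the package's banding or
# vectorization, so they can certify the production implementations.

# Full (unbanded) dissimilarity matrix: entry [i, j] = d(I_j, I_{j+i}),
# i = 1..n-1 lags, defined where i + j <= n.
oracle_dissim_full <- function(imgs, fn) {
  n <- dim(imgs)[3]
  slice <- function(j) matrix(imgs[, , j], dim(imgs)[1], dim(imgs)[2])
  D <- matrix(NA_real_, n - 1, n - 1)
  for (i in seq_len(n - 1)) {
    for (j in seq_len(n)) {
      if (i + j <= n) D[i, j] <- fn(slice(j), slice(j + i))
    }
  }
  D
}

# Average-tie 0-based rank of one value within a row, computed from sorted
# positions (independent of base::rank).
oracle_rank0 <- function(value, row) {
  mean(which(sort(row) == value)) - 1
}

oracle_normalize <- function(D, n_us, variant) {
  R <- D
  for (i in seq_len(nrow(D))) {
    row <- D[i, !is.na(D[i, ])]
    for (j in seq_along(row)) {
      R[i, j] <- if (variant == "ranked") {
        if (length(row) == 1L) 0 else oracle_rank0(row[j], row) / (n_us - i - 1)
      } else {
        if (max(row) > min(row)) (row[j] - min(row)) / (max(row) - min(row))
        else 0
      }
    }
  }
  R
}

# Motion score of one frame: the literal triple sum
# 2 / (|Delta| |s|^2) * sum_d sum_{i=1}^{|s|} sum_{j=s_1}^{s_{|s|-i}} M^d_{ij}.
oracle_frame_score <- function(norm_list, s) {
  n <- length(s)
  if (n < 2L) return(NA_real_)
  total <- 0
  for (M in norm_list) {
    for (i in seq_len(n)) {
      if (n - i >= 1) {
        for (j in s[1]:s[n - i]) total <- total + M[i, j]
      }
    }
  }
  2 * total / (length(norm_list) * n^2)
}

# Whole-scan motion vector straight from the formulas (no banding: all lags).
oracle_motion_vector <- function(scan, measure_fns, variant) {
  n_us <- dim(scan$us_images)[3]
  norms <- lapply(measure_fns, function(fn)
    oracle_normalize(oracle_dissim_full(scan$us_images, fn), n_us, variant))
  frames <- ms_frames(scan)
  vapply(frames, function(f) oracle_frame_score(norms, f$s), numeric(1))
}

# Naive baseline, Eq.-literal: divisor |s| over the |s|-1 consecutive pairs.
oracle_naive_vector <- function(scan, fn) {
  frames <- ms_frames(scan)
  vapply(frames, function(f) {
    s <- f$s
    if (length(s) < 2L) return(NA_real_)
    imgs <- scan$us_images
    slice <- function(j) matrix(imgs[, , j], dim(imgs)[1], dim(imgs)[2])
    total <- 0
    for (j in s[1]:s[length(s) - 1]) {
      total <- total + fn(slice(j), slice(j + 1))
    }
    total / length(s)
  }, numeric(1))
}

# Brute-force average precision over a given ranked candidate list.
oracle_ap <- function(ranked_candidates, events) {
  inside <- function(p) any(events$start <= p & p <= events$end)
  ap <- 0; prev_r <- 0
  for (n in seq_along(ranked_candidates)) {
    preds <- ranked_candidates[seq_len(n)]
    tp <- sum(vapply(preds, inside, logical(1)))
    tp1 <- sum(vapply(seq_len(nrow(events)), function(e)
      any(preds >= events$start[e] & preds <= events$end[e]), logical(1)))
    prec <- tp / n
    rec <- tp1 / nrow(events)
    if (rec > prev_r) {
      ap <- ap + (rec - prev_r) * prec
      prev_r <- rec
    }
  }
  ap
}
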