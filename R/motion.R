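#' Banded pairwise dissimilarity matrix of the US stream
#'
#' Row `i` (the lag) holds `d(I_US(j), I_US(j+i))` for every start index `j`
#' with `i + j <= N_US`; entries beyond that anti-diagonal are undefined and
#' stored as `NA`.  Only the first `K` lags are needed, because an MS frame
#' never spans more than `K = max |s|` US images.
#'
#' @param us_images numeric array `H x W x N_US` (e.g. `scan$us_images`).
#' @param measure a measure name or `msopus_measure`, see [get_measure()].
#' @param K number of lag rows to compute, `1 <= K <= N_US - 1`.
#' @return object of class `msopus_dissim`: list with `values`
#'   (`K x (N_US - 1)` matrix, `NA` where undefined), `measure`, `K`, `n_us`.
#' @export
dissimilarity_matrix <- function(us_images, measure, K) {
  m <- get_measure(measure)
  stopifnot(length(dim(us_images)) == 3L)
  n <- dim(us_images)[3]
  if (n < 2L)
    stop_msopus("need at least 2 US images", class = "msopus_insufficient_data_error")
  if (K < 1L || K > n - 1L)
    stop_msopus("K=%d out of range 1..%d", K, n - 1L, class = "msopus_index_error")
  values <- matrix(NA_real_, nrow = K, ncol = n - 1L)
  hw <- dim(us_images)[1:2]
  slice <- function(j) {  # keep 1 x 1 images as matrices
    x <- us_images[, , j, drop = FALSE]
    dim(x) <- hw
    x
  }
  for (i in seq_len(K)) {
    for (j in seq_len(n - i)) {
      values[i, j] <- m$fn(slice(j), slice(j + i))
    }
  }
  structure(list(values = values, measure = m$name, K = K, n_us = n),
            class = "msopus_dissim")
}

row_lengths <- function(D) D$n_us - seq_len(D$K)

#' Row-wise rank normalization of a dissimilarity matrix
#'
#' Each defined entry of row `i` is replaced by its 0-based rank within the
#' row (average fractional rank on ties) divided by `N_US - i - 1`, the
#' maximal rank, so values land in `[0, 1]`.  A single-entry row maps to 0;
#' a constant row maps to 0.5 everywhere (average-tie convention).  Ranking
#' discards the measure's scale, making different measures commensurable and
#' robust to outlier pairs.
#'
#' @param D an `msopus_dissim` from [dissimilarity_matrix()].
#' @return object of class `msopus_norm` with the same band structure
#'   (`values`, `measure`, `K`, `n_us`) and `kind = "rank"`.
#' @export
rank_normalize <- function(D) {
  stopifnot(inherits(D, "msopus_dissim"))
  values <- D$values
  len <- row_lengths(D)
  for (i in seq_len(D$K)) {
    x <- values[i, seq_len(len[i])]
    r <- rank(x, ties.method = "average") - 1
    values[i, seq_len(len[i])] <- if (len[i] == 1L) 0 else r / (len[i] - 1L)
  }
  structure(list(values = values, measure = D$measure, K = D$K,
                 n_us = D$n_us, kind = "rank"),
            class = "msopus_norm")
}

#' Row-wise min-max normalization of a dissimilarity matrix
#'
#' Each row is affinely mapped so its minimum becomes 0 and its maximum 1;
#' constant rows map to 0.  Unlike [rank_normalize()], a single outlier pair
#' compresses the rest of the row, which is why the ranked variant is the
#' recommended default.
#'
#' @inheritParams rank_normalize
#' @return an `msopus_norm` with `kind = "minmax"`.
#' @export
minmax_normalize <- function(D) {
  stopifnot(inherits(D, "msopus_dissim"))
  values <- D$values
  len <- row_lengths(D)
  for (i in seq_len(D$K)) {
    x <- values[i, seq_len(len[i])]
    rng <- range(x)
    values[i, seq_len(len[i])] <-
      if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else 0
  }
  structure(list(values = values, measure = D$measure, K = D$K,
                 n_us = D$n_us, kind = "minmax"),
            class = "msopus_norm")
}

#' Motion score of one MS frame from normalized matrices
#'
#' Averages, over all measures in the set and over every pair of US images of
#' the frame, the normalized dissimilarity:
#' \deqn{m = \frac{2}{|\Delta| |s|^2} \sum_{d \in \Delta} \sum_{i=1}^{|s|}
#'       \sum_{j=s_1}^{s_{|s|-i}} M^d_{ij},}
#' where `M` is the rank- or min-max-normalized matrix and inner sums with an
#' empty index range contribute 0.  Because pairs at every lag enter the sum,
#' steady drift (whose distant pairs are very dissimilar) scores higher than
#' zero-mean jitter of the same per-step magnitude.
#'
#' @param norms a single `msopus_norm` or a list of them (one per measure),
#'   all sharing the band structure.
#' @param s ascending, contiguous US index sequence of the frame.
#' @return the frame's score in `[0, (|s|-1)/|s|]`, or `NA` (with a warning)
#'   when `|s| < 2`.
#' @export
frame_score <- function(norms, s) {
  if (inherits(norms, "msopus_norm")) norms <- list(norms)
  stopifnot(length(norms) >= 1L,
            all(vapply(norms, inherits, logical(1), "msopus_norm")))
  n <- length(s)
  if (n < 2L) {
    warning("frame has fewer than 2 US images; score is NA", call. = FALSE)
    return(NA_real_)
  }
  if (any(diff(s) != 1L))
    stop_msopus("US index sequence s must be contiguous",
                class = "msopus_index_error")
  if (norms[[1]]$K < n - 1L)
    stop_msopus("normalized matrix has K=%d rows, frame needs %d",
                norms[[1]]$K, n - 1L, class = "msopus_index_error")
  total <- 0
  for (M in norms) {
    V <- M$values
    for (i in seq_len(n - 1L)) {
      total <- total + sum(V[i, s[1]:(s[1] + n - i - 1L)])
    }
  }
  2 * total / (length(norms) * n^2)
}

#' Motion score vector of a whole scan
#'
#' Computes the banded dissimilarity matrix once per measure (with
#' `K = max_us_per_frame(scan)` lags), normalizes it row-wise, and scores
#' every sliding MS frame.  Frames with fewer than two US images get `NA`.
#'
#' @param scan an `msopus_scan`.
#' @param measures character vector of measure names and/or
#'   `msopus_measure` objects; default `c("znxc", "ssim")`, the best
#'   validated combination.
#' @param variant `"ranked"` (default, recommended) or `"normalized"`
#'   (min-max).
#' @return a `data.frame` of class `msopus_motion` with columns
#'   `frame_index`, `oa_start_index`, `n_us`, `score`, `variant`, `measures`.
#' @export
motion_vector <- function(scan, measures = c("znxc", "ssim"),
                          variant = c("ranked", "normalized")) {
  variant <- match.arg(variant)
  if (!is.list(measures)) measures <- as.list(measures)
  ms <- lapply(measures, get_measure)
  frames <- ms_frames(scan)
  n_us_per_frame <- vapply(frames, function(f) length(f$s), integer(1))
  K <- min(max(0L, n_us_per_frame), dim(scan$us_images)[3] - 1L)
  scores <- rep(NA_real_, length(frames))
  if (K >= 1L) {
    normalize <- if (variant == "ranked") rank_normalize else minmax_normalize
    norms <- lapply(ms, function(m)
      normalize(dissimilarity_matrix(scan$us_images, m, K)))
    for (k in seq_along(frames)) {
      if (n_us_per_frame[k] >= 2L)
        scores[k] <- frame_score(norms, frames[[k]]$s)
    }
  }
  if (any(n_us_per_frame < 2L))
    warning(sprintf("%d frame(s) with fewer than 2 US images scored as NA",
                    sum(n_us_per_frame < 2L)), call. = FALSE)
  motion_df(scores, n_us_per_frame, variant,
            paste(vapply(ms, `[[`, character(1), "name"), collapse = "+"))
}

#' Naive per-frame motion baseline
#'
#' The mean dissimilarity of *consecutive* US image pairs within each frame,
#' \eqn{m_0 = |s|^{-1} \sum_{j=s_1}^{s_{|s|-1}} d(I_US(j), I_US(j+1))}
#' (the divisor is `|s|` although the sum has `|s| - 1` terms, exactly as the
#' baseline is conventionally written).  Consecutive-pair comparison cannot
#' distinguish steady drift from jitter, which is what the Motion score
#' remedies.
#'
#' @param scan an `msopus_scan`.
#' @param measure a single measure name or `msopus_measure`.
#' @return an `msopus_motion` data frame with `variant = "naive"`.
#' @export
naive_motion_vector <- function(scan, measure = "l2") {
  m <- get_measure(measure)
  frames <- ms_frames(scan)
  n_us_per_frame <- vapply(frames, function(f) length(f$s), integer(1))
  scores <- rep(NA_real_, length(frames))
  if (dim(scan$us_images)[3] >= 2L && any(n_us_per_frame >= 2L)) {
    D <- dissimilarity_matrix(scan$us_images, m, K = 1L)
    for (k in seq_along(frames)) {
      s <- frames[[k]]$s
      n <- length(s)
      if (n >= 2L)
        scores[k] <- sum(D$values[1L, s[1]:(s[1] + n - 2L)]) / n
    }
  }
  if (any(n_us_per_frame < 2L))
    warning(sprintf("%d frame(s) with fewer than 2 US images scored as NA",
                    sum(n_us_per_frame < 2L)), call. = FALSE)
  motion_df(scores, n_us_per_frame, "naive", m$name)
}

motion_df <- function(scores, n_us, variant, measures) {
  out <- data.frame(frame_index = seq_along(scores),
                    oa_start_index = seq_along(scores),
                    n_us = n_us,
                    score = scores,
                    variant = variant,
                    measures = measures,
                    stringsAsFactors = FALSE)
  class(out) <- c("msopus_motion", "data.frame")
  out
}

# Accept either an msopus_motion data frame or a bare numeric vector.
motion_scores <- function(m) {
  if (inherits(m, "msopus_motion") || is.data.frame(m)) return(m$score)
  stopifnot(is.numeric(m))
  as.double(m)
}

#' Read and write Motion score tables
#'
#' CSV with columns `frame_index`, `oa_start_index`, `n_us`, `score`,
#' `variant`, `measures`; missing scores are empty cells.
#'
#' @param m an `msopus_motion` data frame.
#' @param path CSV file path.
#' @return `write_scores` returns `path` invisibly; `read_scores` returns an
#'   `msopus_motion` data frame.
#' @export
write_scores <- function(m, path) {
  stopifnot(is.data.frame(m))
  utils::write.csv(m, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  out <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  need <- c("frame_index", "oa_start_index", "n_us", "score", "variant", "measures")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop_msopus("scores file %s lacks column(s): %s", path,
                paste(missing, collapse = ", "), class = "msopus_format_error")
  out$score <- as.double(out$score)
  class(out) <- c("msopus_motion", "data.frame")
  out
}
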