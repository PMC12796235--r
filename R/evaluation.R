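#' Aggregate human stationary-interval annotations to per-frame labels
#'
#' Each annotator marks inclusive US-index intervals as stationary.  Summing
#' across the `A` annotators scores every US image 0..A; each MS frame gets
#' the mean score of its corresponding US images, and frames with a mean
#' score of at least `A/2` (1.5 for three annotators) count as stationary.
#' Frames with no corresponding US image are labelled non-stationary and
#' flagged.
#'
#' @param annots list with one element per annotator: a list with fields
#'   `annotator` (name) and `intervals` (n x 2 matrix/list of inclusive
#'   1-based US index ranges, non-overlapping within an annotator).  See
#'   [read_annotations()].
#' @param scan the annotated `msopus_scan`.
#' @return list with `us_scores` (integer 0..A per US image), `frame_scores`
#'   (mean per MS frame, `NA` for frames with empty `s`), `stationary`
#'   (logical per frame), `n_annotators`, `threshold`.
#' @export
aggregate_annotations <- function(annots, scan) {
  n_us <- dim(scan$us_images)[3]
  a_count <- length(annots)
  us_scores <- integer(n_us)
  for (ann in annots) {
    iv <- interval_matrix(ann$intervals)
    if (nrow(iv)) {
      if (any(iv[, 1] < 1 | iv[, 2] > n_us | iv[, 1] > iv[, 2]))
        stop_msopus("annotation interval outside 1..%d for annotator '%s'",
                    n_us, ann$annotator %||% "?",
                    class = "msopus_validation_error")
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
        stop_msopus("overlapping intervals for annotator '%s'",
                    ann$annotator %||% "?", class = "msopus_validation_error")
      for (r in seq_len(nrow(iv)))
        us_scores[iv[r, 1]:iv[r, 2]] <- us_scores[iv[r, 1]:iv[r, 2]] + 1L
    }
  }
  frames <- ms_frames(scan)
  frame_scores <- vapply(frames, function(f)
    if (length(f$s)) mean(us_scores[f$s]) else NA_real_, numeric(1))
  if (anyNA(frame_scores))
    warning(sprintf("%d frame(s) without US images labelled non-stationary",
                    sum(is.na(frame_scores))), call. = FALSE)
  threshold <- a_count / 2
  list(us_scores = us_scores,
       frame_scores = frame_scores,
       stationary = a_count > 0 & !is.na(frame_scores) &
         frame_scores >= threshold,
       n_annotators = a_count,
       threshold = threshold)
}

interval_matrix <- function(iv) {
  if (is.null(iv) || length(iv) == 0L)
    return(matrix(integer(0), ncol = 2))
  if (is.list(iv)) iv <- do.call(rbind, lapply(iv, as.integer))
  iv <- matrix(as.integer(iv), ncol = 2)
  iv
}

#' Maximal runs of stationary frames (target events)
#'
#' @param mask logical vector per MS frame (`NA` treated as `FALSE`).
#' @return data.frame with columns `start`, `end` (inclusive frame indices),
#'   disjoint, ascending, non-adjacent.
#' @export
events_from_mask <- function(mask) {
  mask <- !is.na(mask) & mask
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Event-level precision and recall of a frame selection
#'
#' A predicted frame inside any target event is a true positive (TP); outside
#' every event, a false positive (FP).  `TP1` credits at most one prediction
#' per event; events without a prediction are false negatives (FN).
#' `precision = TP / (TP + FP)` and `recall = TP1 / (TP1 + FN)`; an empty
#' denominator yields `NA`.
#'
#' @param preds distinct predicted MS frame indices (or an
#'   `msopus_selection`).
#' @param events data.frame with `start`, `end` columns, see
#'   [events_from_mask()].
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`, `tp1`.
#' @export
precision_recall <- function(preds, events) {
  if (inherits(preds, "msopus_selection")) preds <- preds$frame_indices
  preds <- as.integer(preds)
  if (anyDuplicated(preds))
    stop_msopus("predictions must be distinct frame indices",
                class = "msopus_validation_error")
  n_ev <- nrow(events)
  in_event <- function(p) events$start <= p & p <= events$end
  hit <- vapply(preds, function(p) any(in_event(p)), logical(1))
  tp <- sum(hit)
  fp <- length(preds) - tp
  tp1 <- if (n_ev)
    sum(vapply(seq_len(n_ev), function(e)
      any(preds >= events$start[e] & preds <= events$end[e]), logical(1)))
  else 0L
  fn <- n_ev - tp1
  list(precision = if (length(preds)) tp / (tp + fp) else NA_real_,
       recall = if (n_ev) tp1 / (tp1 + fn) else NA_real_,
       tp = tp, fp = fp, fn = as.integer(fn), tp1 = as.integer(tp1))
}

#' Average precision of the Motion score ranking of one scan
#'
#' Sweeps the number of selected frames over the whole pool of
#' distance-respecting local minima (the only frames the selector can ever
#' emit), ranked by ascending score, and integrates the precision-recall
#' curve stepwise: `AP = sum over n of (R_n - R_{n-1}) * P_n` (no
#' interpolation).  AP depends only on the ordering of the minima, so it is
#' invariant to strictly monotone transforms of the motion vector.
#'
#' @param m an `msopus_motion` data frame or numeric score vector.
#' @param events target events, see [events_from_mask()].
#' @param d_min minimum separation, `NULL` for [default_min_distance()].
#' @return AP in `[0, 1]`, or `NA` when there are no events.
#' @export
average_precision <- function(m, events, d_min = NULL) {
  if (nrow(events) == 0L) {
    warning("no target events; AP undefined", call. = FALSE)
    return(NA_real_)
  }
  sel <- select_stationary_frames(m, d_min = d_min, n_peaks = Inf)
  cand <- sel$frame_indices[order(sel$scores, sel$frame_indices)]
  if (!length(cand)) return(0)
  ap <- 0
  prev_recall <- 0
  for (n in seq_along(cand)) {
    pr <- precision_recall(cand[seq_len(n)], events)
    if (pr$recall > prev_recall) {
      ap <- ap + (pr$recall - prev_recall) * pr$precision
      prev_recall <- pr$recall
    }
  }
  ap
}

#' Mean average precision over a collection of scans
#'
#' @param aps numeric vector (or list) of per-scan AP values; `NA` entries
#'   (scans with no events) are excluded with a warning.
#' @return arithmetic mean of the defined APs.
#' @export
mean_average_precision <- function(aps) {
  aps <- as.double(unlist(aps))
  if (anyNA(aps)) {
    warning(sprintf("%d scan(s) with undefined AP excluded", sum(is.na(aps))),
            call. = FALSE)
    aps <- aps[!is.na(aps)]
  }
  if (!length(aps)) return(NA_real_)
  mean(aps)
}

#' Read and write annotation files
#'
#' JSON layout: an array of `{"annotator": name,
#' "intervals": [[us_start, us_end], ...]}` objects with inclusive 1-based
#' US indices.
#'
#' @param path JSON file path.
#' @param annots annotation list as consumed by [aggregate_annotations()].
#' @return `read_annotations` returns the annotation list; `write_annotations`
#'   returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(a)
    list(annotator = a$annotator %||% "?",
         intervals = interval_matrix(a$intervals)))
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annots, path) {
  obj <- lapply(annots, function(a) {
    iv <- interval_matrix(a$intervals)
    list(annotator = a$annotator %||% "?",
         intervals = lapply(seq_len(nrow(iv)), function(r) as.integer(iv[r, ])))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
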