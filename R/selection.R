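#' Default minimum peak separation
#'
#' One twentieth of the scan length (in MS frames), floored, and clamped to
#' at least 1.  Separations below the number of US images per frame would
#' select stationary frames sharing single-wavelength images; much larger
#' values risk missing genuine stationary positions.
#'
#' @param n_ms number of MS frames in the scan.
#' @return integer separation `d_min >= 1`.
#' @export
default_min_distance <- function(n_ms) {
  stopifnot(n_ms >= 1)
  max(1L, as.integer(floor(n_ms / 20)))
}

# Strict local minima of a vector with NAs.
# NAs split the vector into segments; minima are sought per segment with the
# segment endpoints excluded.  A plateau (run of equal values) lower than
# both neighbors is represented by its midpoint, floor((start+end)/2).
local_minima <- function(x) {
  n <- length(x)
  out <- integer(0)
  seg <- rle(!is.na(x))
  ends <- cumsum(seg$lengths)
  starts <- ends - seg$lengths + 1L
  for (si in which(seg$values)) {
    a <- starts[si]; b <- ends[si]
    if (b - a < 2L) next
    v <- x[a:b]
    runs <- rle(v)
    re <- cumsum(runs$lengths)
    rs <- re - runs$lengths + 1L
    nr <- length(runs$values)
    if (nr < 3L) next
    for (ri in 2L:(nr - 1L)) {
      if (runs$values[ri] < runs$values[ri - 1L] &&
          runs$values[ri] < runs$values[ri + 1L]) {
        mid <- (rs[ri] + re[ri]) %/% 2L
        out <- c(out, a + mid - 1L)
      }
    }
  }
  out
}

# Distance filter in the style of standard peak finders: candidates are
# visited in priority order (lowest score first, earlier index on ties) and
# kept only if at least d_min frames away from every already kept one.
filter_by_distance <- function(idx, val, d_min) {
  ord <- order(val, idx)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(idx[i] - kept) >= d_min))
      kept <- c(kept, idx[i])
  }
  sort(kept)
}

#' Select stationary MS frames as Motion score minima
#'
#' Finds strict local minima of the motion vector (vector endpoints excluded;
#' plateaus represented by their midpoints; `NA` gaps split the vector into
#' independently searched segments), enforces a pairwise separation of at
#' least `d_min` frames by keeping lower-valued minima first, sorts the
#' survivors by ascending score (ties toward the earlier frame), and returns
#' the first `n_peaks`.
#'
#' @param m an `msopus_motion` data frame or a numeric score vector.
#' @param d_min minimum index separation between selected frames;
#'   `NULL` (default) uses [default_min_distance()].
#' @param n_peaks maximum number of frames to select (default 5); fewer are
#'   returned when fewer minima exist.  `Inf` returns every
#'   distance-respecting minimum.
#' @return object of class `msopus_selection`: list with `frame_indices` and
#'   `scores` (ascending in score), `d_min`, `n_peaks_requested`.
#' @export
select_stationary_frames <- function(m, d_min = NULL, n_peaks = 5) {
  x <- motion_scores(m)
  if (is.null(d_min)) d_min <- default_min_distance(length(x))
  stopifnot(d_min >= 1, n_peaks >= 1)
  if (all(is.na(x))) {
    warning("motion vector is all missing; empty selection", call. = FALSE)
    cand <- integer(0)
  } else {
    cand <- local_minima(x)
    cand <- filter_by_distance(cand, x[cand], d_min)
  }
  ord <- order(x[cand], cand)
  take <- utils::head(ord, n_peaks)
  structure(list(frame_indices = cand[take],
                 scores = x[cand][take],
                 d_min = as.integer(d_min),
                 n_peaks_requested = n_peaks),
            class = "msopus_selection")
}

#' @export
print.msopus_selection <- function(x, ...) {
  cat(sprintf("Stationary-frame selection (%d of up to %s requested, d_min=%d)\n",
              length(x$frame_indices), format(x$n_peaks_requested), x$d_min))
  if (length(x$frame_indices))
    print(data.frame(frame = x$frame_indices, score = x$scores))
  invisible(x)
}

#' Read and write frame selections as JSON
#'
#' @param sel an `msopus_selection`.
#' @param path JSON file path.
#' @param extra named list merged into the JSON object (e.g. provenance).
#' @return `write_selection` returns `path` invisibly; `read_selection`
#'   returns an `msopus_selection`.
#' @export
write_selection <- function(sel, path, extra = list()) {
  stopifnot(inherits(sel, "msopus_selection"))
  obj <- c(list(frame_indices = as.integer(sel$frame_indices),
                scores = as.double(sel$scores),
                d_min = sel$d_min,
                n_peaks = if (is.finite(sel$n_peaks_requested))
                  as.integer(sel$n_peaks_requested) else "all"),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(frame_indices = as.integer(obj$frame_indices),
                 scores = as.double(obj$scores),
                 d_min = as.integer(obj$d_min),
                 n_peaks_requested = if (identical(obj$n_peaks, "all")) Inf
                                     else as.numeric(obj$n_peaks)),
            class = "msopus_selection")
}
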