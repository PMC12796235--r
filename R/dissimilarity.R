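#' Image dissimilarity measures
#'
#' The Motion score compares the US images acquired during an MS frame with a
#' configurable set of dissimilarity measures \eqn{\Delta}.  Four measures are
#' built in:
#'
#' * `l2` — Euclidean norm of the pixelwise difference, range `[0, Inf)`.
#' * `xcorr` — negated mean elementwise product (unnormalized
#'   cross-correlation at zero displacement), lower is more similar for
#'   nonnegative images.
#' * `znxc` — `1 - r`, with `r` the zero-mean, unit-variance (Pearson)
#'   correlation of the flattened pixels, range `[0, 2]`.
#' * `ssim` — `1 -` mean structural similarity (Gaussian window 11,
#'   sigma 1.5), range `[0, 2]`.
#'
#' Every measure is symmetric and attains its range minimum at `d(a, a)` for
#' non-degenerate images.  User-defined measures (for example an optical-flow
#' magnitude) can be plugged in via [as_measure()].
#'
#' @name dissimilarity-measures
NULL

check_image_pair <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b))
    stop_msopus("images must be 2-D matrices", class = "msopus_shape_error")
  if (!identical(dim(a), dim(b)))
    stop_msopus("image shapes differ: %s vs %s",
                paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"),
                class = "msopus_shape_error")
  invisible(TRUE)
}

#' @rdname dissimilarity-measures
#' @param a,b equally shaped numeric matrices (images).
#' @return a single finite numeric dissimilarity.
#' @export
d_l2 <- function(a, b) {
  check_image_pair(a, b)
  sqrt(sum((a - b)^2))
}

#' @rdname dissimilarity-measures
#' @export
d_xcorr <- function(a, b) {
  check_image_pair(a, b)
  -mean(a * b)
}

#' @rdname dissimilarity-measures
#' @details For `znxc`, degenerate (constant) images carry no correlation
#'   information: two constant images give 0, exactly one constant image
#'   gives the neutral value 1.
#' @export
d_znxc <- function(a, b) {
  check_image_pair(a, b)
  va <- as.vector(a); vb <- as.vector(b)
  ca <- diff(range(va)) == 0
  cb <- diff(range(vb)) == 0
  if (ca && cb) return(0)
  if (ca || cb) return(1)
  1 - stats::cor(va, vb)
}

#' @rdname dissimilarity-measures
#' @param L dynamic range used in the SSIM stabilizers
#'   `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`; default is the per-pair range
#'   `max(a, b) - min(a, b)`.
#' @param window,sigma Gaussian window size (pixels, odd) and standard
#'   deviation; the SSIM map is computed on the valid (un-padded) region and
#'   averaged.
#' @export
d_ssim <- function(a, b, L = NULL, window = 11L, sigma = 1.5) {
  check_image_pair(a, b)
  if (min(dim(a)) < window)
    stop_msopus("image (%s) smaller than the %d-pixel SSIM window",
                paste(dim(a), collapse = "x"), window,
                class = "msopus_shape_error")
  if (is.null(L)) L <- max(a, b) - min(a, b)
  if (L == 0) return(0)  # identical constant images
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  g <- gaussian_kernel(window, sigma)
  Gr <- conv_band_valid(nrow(a), g)
  Gc <- t(conv_band_valid(ncol(a), g))
  filt <- function(x) Gr %*% x %*% Gc
  mu_a <- filt(a); mu_b <- filt(b)
  var_a <- filt(a * a) - mu_a^2
  var_b <- filt(b * b) - mu_b^2
  cov_ab <- filt(a * b) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  1 - mean(ssim_map)
}

#' Wrap a function as a named dissimilarity measure
#'
#' Hook for user-supplied measures (e.g. an optical-flow based one); the
#' function must be symmetric and minimal at identical images.
#'
#' @param fn function of two equally shaped matrices returning one number.
#' @param name identifier used in outputs and configs.
#' @param range documented output interval, `c(min, max)`.
#' @return an object of class `msopus_measure`.
#' @export
as_measure <- function(fn, name, range = c(0, Inf)) {
  stopifnot(is.function(fn), is.character(name), length(name) == 1L)
  structure(list(name = name, fn = fn, range = range),
            class = "msopus_measure")
}

.measure_registry <- list(
  l2    = function() as_measure(d_l2, "l2", c(0, Inf)),
  xcorr = function() as_measure(d_xcorr, "xcorr", c(-Inf, Inf)),
  znxc  = function() as_measure(d_znxc, "znxc", c(0, 2)),
  ssim  = function() as_measure(d_ssim, "ssim", c(0, 2))
)

#' Resolve a dissimilarity measure by name
#'
#' @param x a measure name (`"l2"`, `"xcorr"`, `"znxc"`, `"ssim"`) or an
#'   `msopus_measure` (returned unchanged).
#' @return an `msopus_measure`.
#' @export
get_measure <- function(x) {
  if (inherits(x, "msopus_measure")) return(x)
  if (is.character(x) && length(x) == 1L && x %in% names(.measure_registry))
    return(.measure_registry[[x]]())
  stop_msopus("unknown dissimilarity measure: %s", toString(x),
              class = "msopus_measure_error")
}

#' @rdname get_measure
#' @export
list_measures <- function() names(.measure_registry)
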