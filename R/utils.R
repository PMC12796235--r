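#' msopus: motion quantification for multispectral optoacoustic-ultrasound
#'
#' See the package README and the methods vignette for the scientific
#' background; start at [motion_vector()] and [select_stationary_frames()].
#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round doubles to the nearest IEEE single-precision value
#'
#' Scan images are stored as float32 on disk; snapping simulated images to the
#' float32 grid makes save/load round trips bit-exact.
#' @param x numeric vector or array.
#' @return `x` with every value representable in single precision.
#' @keywords internal
snap_float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.double(x), raw(), size = 4L),
                 what = "double", n = length(x), size = 4L)
  dim(out) <- d
  out
}

# Evaluate expr with a private RNG stream seeded by `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Derive `n` independent substream seeds (< 2^31) from one root seed.
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Banded Toeplitz matrix B (n x n) such that B %*% x is the zero-padded
# "same" 1-D convolution of x with `kernel` (odd length).
conv_band_same <- function(n, kernel) {
  k <- length(kernel)
  stopifnot(k %% 2 == 1)
  r <- (k - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    B[cbind(idx[ok], src[ok])] <- B[cbind(idx[ok], src[ok])] + kernel[off + r + 1L]
  }
  B
}

# Banded matrix G ((n-k+1) x n) such that G %*% x is the "valid" 1-D
# correlation of x with `kernel`.
conv_band_valid <- function(n, kernel) {
  k <- length(kernel)
  stopifnot(n >= k)
  m <- n - k + 1L
  G <- matrix(0, m, n)
  for (i in seq_len(m)) G[i, i:(i + k - 1L)] <- kernel
  G
}

gaussian_kernel <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

stop_msopus <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "msopus_error", "error", "condition")))
}
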