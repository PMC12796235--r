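#' Arrange an MS frame as a pixel-by-wavelength matrix
#'
#' Rows are pixels (column-major image order), columns the frame's OA images
#' sorted by ascending wavelength, so row `p` is the measured absorption
#' spectrum of pixel `p`.
#'
#' @param scan an `msopus_scan`.
#' @param k MS frame start index.
#' @return numeric matrix `p x N_lambda`; attributes `image_dim` (H, W) and
#'   `wavelengths` record the frame geometry.
#' @export
frame_to_matrix <- function(scan, k) {
  n_ms <- n_ms_frames(scan)
  if (k < 1 || k > n_ms)
    stop_msopus("frame index k=%s out of range 1..%d", toString(k), n_ms,
                class = "msopus_index_error")
  n_lambda <- length(scan$wavelengths)
  idx <- k:(k + n_lambda - 1L)
  idx <- idx[order(scan$oa_wavelengths[idx])]
  h <- dim(scan$oa_images)[1]; w <- dim(scan$oa_images)[2]
  I <- matrix(scan$oa_images[, , idx], nrow = h * w, ncol = n_lambda)
  attr(I, "image_dim") <- c(h, w)
  attr(I, "wavelengths") <- scan$wavelengths
  I
}

#' @rdname frame_to_matrix
#' @param I a `p x N_lambda` matrix.
#' @param image_dim `c(H, W)` with `H * W == nrow(I)`; default taken from the
#'   matrix attribute.
#' @return `matrix_to_frame` returns the `H x W x N_lambda` image stack.
#' @export
matrix_to_frame <- function(I, image_dim = attr(I, "image_dim")) {
  stopifnot(prod(image_dim) == nrow(I))
  array(I, c(image_dim[1], image_dim[2], ncol(I)))
}

#' Bundled chromophore absorption spectra
#'
#' Loads the packaged spectra table (deoxyhemoglobin `hb`, oxyhemoglobin
#' `hbo2`, `water`, `lipid`) and linearly interpolates each component onto
#' the requested wavelength grid.  The bundled curves are synthetic smooth
#' approximations reproducing the qualitative literature features (Hb 760 nm
#' bump, HbO2 rise beyond 800 nm, lipid 930 nm peak, water 970 nm peak); see
#' the file header in `inst/extdata/chromophore_spectra_synthetic.csv`.
#'
#' @param wavelengths target grid in nm; must lie within the tabulated range.
#' @param components subset of component names (default all four).
#' @param file alternative spectra CSV with a `wavelength_nm` column.
#' @return matrix `k x |Lambda|` with component rownames and a `wavelengths`
#'   attribute.
#' @export
chromophore_spectra <- function(wavelengths,
                                components = c("hb", "hbo2", "water", "lipid"),
                                file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "chromophore_spectra_synthetic.csv",
                        package = "msopus", mustWork = TRUE)
  tab <- utils::read.csv(file, comment.char = "#")
  missing <- setdiff(components, names(tab))
  if (length(missing))
    stop_msopus("spectra table lacks component(s): %s",
                paste(missing, collapse = ", "), class = "msopus_format_error")
  if (min(wavelengths) < min(tab$wavelength_nm) ||
      max(wavelengths) > max(tab$wavelength_nm))
    stop_msopus("requested wavelengths outside tabulated range %g-%g nm",
                min(tab$wavelength_nm), max(tab$wavelength_nm),
                class = "msopus_validation_error")
  W <- t(vapply(components, function(comp)
    stats::approx(tab$wavelength_nm, tab[[comp]], xout = wavelengths)$y,
    numeric(length(wavelengths))))
  rownames(W) <- components
  attr(W, "wavelengths") <- as.double(wavelengths)
  W
}

#' Non-negative linear spectral unmixing against known spectra
#'
#' Solves, independently for every pixel row of `I`,
#' \deqn{C = \arg\min_{C \ge 0} \| I - C W \|_F,}
#' the non-negative least-squares decomposition of the measured pixel spectra
#' into the component spectra `W`.  For up to 10 components the exact
#' solution is found by enumerating all active sets and solving each
#' unconstrained subproblem for all pixels at once (vectorized and
#' deterministic); larger `k` falls back to a per-pixel Lawson-Hanson solver
#' (`pracma::lsqnonneg`).
#'
#' @param I `p x |Lambda|` matrix of pixel spectra, see [frame_to_matrix()].
#' @param W `k x |Lambda|` matrix of component spectra; if both `I` and `W`
#'   carry a `wavelengths` attribute the grids must match exactly (no silent
#'   interpolation).
#' @return object of class `msopus_unmix`: list with `C` (`p x k`,
#'   non-negative), `W`, `E` (relative L2,1 residual, see
#'   [unmix_residual()]), `method = "nnls"`.
#' @export
nnls_unmix <- function(I, W) {
  wl_i <- attr(I, "wavelengths"); wl_w <- attr(W, "wavelengths")
  if (!is.null(wl_i) && !is.null(wl_w) && !isTRUE(all.equal(wl_i, wl_w)))
    stop_msopus("wavelength grids of frame and spectra differ",
                class = "msopus_validation_error")
  if (ncol(I) != ncol(W))
    stop_msopus("frame has %d wavelengths but spectra have %d",
                ncol(I), ncol(W), class = "msopus_validation_error")
  k <- nrow(W)
  C <- if (k <= 10L) nnls_enumerate(I, W) else nnls_lawson(I, W)
  dimnames(C) <- list(NULL, rownames(W))
  structure(list(C = C, W = W, E = unmix_residual(I, C, W), method = "nnls"),
            class = "msopus_unmix")
}

# Exact NNLS by active-set enumeration, vectorized over pixels: for every
# support S solve the unconstrained LS restricted to S for all pixels in one
# QR solve, keep feasible (C >= 0) candidates, and take the per-pixel
# feasible solution with the smallest residual.  The optimal support is
# always enumerated, so this attains the NNLS optimum.
nnls_enumerate <- function(I, W) {
  p <- nrow(I); k <- nrow(W)
  best_C <- matrix(0, p, k)
  best_res <- rowSums(I^2)              # support = empty set, C = 0
  for (code in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    A <- t(W[S, , drop = FALSE])        # |Lambda| x |S|
    qrA <- qr(A)
    if (qrA$rank < length(S)) next      # degenerate support; a subset covers it
    cf <- t(qr.coef(qrA, t(I)))         # p x |S|
    feas <- rowSums(cf < -1e-12) == 0L
    if (!any(feas)) next
    cf[cf < 0] <- 0
    res <- rowSums((I - cf %*% W[S, , drop = FALSE])^2)
    upd <- feas & res < best_res - 1e-12 * (1 + best_res)
    if (any(upd)) {
      best_res[upd] <- res[upd]
      best_C[upd, ] <- 0
      best_C[upd, S] <- cf[upd, , drop = FALSE]
    }
  }
  best_C
}

nnls_lawson <- function(I, W) {
  A <- t(W)
  t(apply(I, 1L, function(y) pracma::lsqnonneg(A, y)$x))
}

#' Relative L2,1 unmixing residual
#'
#' The spectral-quality metric
#' \deqn{E(I, C, W) = \frac{\|(I - C W)^T\|_{2,1}}{\|I^T\|_{2,1}},}
#' i.e. the sum over pixels of the Euclidean norms of the residual spectra,
#' relative to the same norm of the measured spectra.  `E = 0` for a perfect
#' reconstruction and `E = 1` for `C = 0`; motion-corrupted frames, whose
#' pixel spectra mix neighboring tissue, cannot be explained by the linear
#' mixing model and show elevated `E`.
#'
#' @param I `p x |Lambda|` measured pixel spectra.
#' @param C `p x k` non-negative coefficients.
#' @param W `k x |Lambda|` component spectra.
#' @return `E >= 0`, or `NA` (with a warning) when `I` has zero norm.
#' @export
unmix_residual <- function(I, C, W) {
  stopifnot(nrow(C) == nrow(I), ncol(C) == nrow(W), ncol(W) == ncol(I))
  den <- sum(sqrt(rowSums(I^2)))
  if (den == 0) {
    warning("zero-norm frame; unmixing residual undefined", call. = FALSE)
    return(NA_real_)
  }
  num <- sum(sqrt(rowSums((I - C %*% W)^2)))
  num / den
}

#' Blind spectral unmixing by non-negative matrix factorization
#'
#' Factorizes `I ~ C W` with `C, W >= 0` by multiplicative (Lee-Seung)
#' updates of the Frobenius objective, starting from a deterministic
#' NNDSVD-style initialization whose zero entries are filled with small
#' seeded uniform values.  The reconstruction error is non-increasing across
#' iterations; updates stop when its relative decrease falls below `tol` or
#' after `max_iter` iterations.
#'
#' @param I `p x |Lambda|` matrix of pixel spectra; negative entries
#'   (reconstruction artifacts) are clipped to 0 with a warning.
#' @param k number of components, matched to the number of expected
#'   absorbers (the phantom preset uses `k = 4`).
#' @param seed integer seed for the initialization fill-in.
#' @param max_iter,tol iteration cap and relative-improvement tolerance.
#' @return an `msopus_unmix` with `C`, learned `W`, `E`, `method = "nmf"`,
#'   `k`, `seed`, `iterations`, `converged`, and the per-iteration
#'   reconstruction error `err_trace`.
#' @export
nmf_blind_unmix <- function(I, k, seed = 1L, max_iter = 1000L, tol = 1e-6) {
  stopifnot(k >= 1)
  if (k > min(dim(I)))
    stop_msopus("k=%d exceeds min(p, |Lambda|) = %d", k, min(dim(I)),
                class = "msopus_validation_error")
  if (any(I < 0)) {
    warning("negative intensities clipped to 0 for NMF", call. = FALSE)
    I[I < 0] <- 0
  }
  init <- nndsvd_init(I, k, seed)
  C <- init$C; W <- init$W
  eps <- .Machine$double.eps
  err <- sqrt(sum((I - C %*% W)^2))
  err_trace <- err
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    C <- C * (I %*% t(W)) / (C %*% W %*% t(W) + eps)
    W <- W * (t(C) %*% I) / (t(C) %*% C %*% W + eps)
    new_err <- sqrt(sum((I - C %*% W)^2))
    err_trace <- c(err_trace, new_err)
    if ((err - new_err) / max(err, eps) < tol) {
      err <- new_err
      converged <- TRUE
      break
    }
    err <- new_err
  }
  structure(list(C = C, W = W, E = unmix_residual(I, C, W), method = "nmf",
                 k = as.integer(k), seed = as.integer(seed),
                 iterations = iter, converged = converged,
                 tol = tol, max_iter = as.integer(max_iter),
                 err_trace = err_trace),
            class = "msopus_unmix")
}

# NNDSVD: SVD-based non-negative initialization (Boutsidis & Gallopoulos).
# Zero entries are filled with small seeded uniform noise so multiplicative
# updates can move every element.
nndsvd_init <- function(I, k, seed) {
  sv <- svd(I, nu = k, nv = k)
  p <- nrow(I); m <- ncol(I)
  C <- matrix(0, p, k); W <- matrix(0, k, m)
  C[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  W[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_un <- sqrt(sum(un^2))
      n_vp <- sqrt(sum(vp^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        sig <- n_up * n_vp
        if (sig > 0) {
          C[, j] <- sqrt(sv$d[j] * sig) * up / n_up
          W[j, ] <- sqrt(sv$d[j] * sig) * vp / n_vp
        }
      } else {
        sig <- n_un * n_vn
        C[, j] <- sqrt(sv$d[j] * sig) * un / n_un
        W[j, ] <- sqrt(sv$d[j] * sig) * vn / n_vn
      }
    }
  }
  fill <- mean(I) * 1e-2 + .Machine$double.eps
  with_seed(seed, {
    zc <- C == 0
    C[zc] <- fill * stats::runif(sum(zc))
    zw <- W == 0
    W[zw] <- fill * stats::runif(sum(zw))
  })
  list(C = C, W = W)
}

#' @export
print.msopus_unmix <- function(x, ...) {
  cat(sprintf("Spectral unmixing (%s): %d pixels x %d components, E = %.4g\n",
              x$method, nrow(x$C), ncol(x$C), x$E))
  invisible(x)
}

#' Write an unmixing result to HDF5
#'
#' Datasets `/C` (pixels x components) and `/W` (components x wavelengths);
#' root attributes `E`, `method`, and `seed` (NMF only).
#'
#' @param x an `msopus_unmix`.
#' @param path output HDF5 path (overwritten).
#' @return `path`, invisibly.
#' @export
write_unmix <- function(x, path) {
  stopifnot(inherits(x, "msopus_unmix"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(unname(x$C), path, "C")
  rhdf5::h5write(unname(x$W), path, "W")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.double(x$E), fid, "E")
  rhdf5::h5writeAttribute(x$method, fid, "method")
  rhdf5::h5writeAttribute(as.integer(x$seed %||% NA_integer_), fid, "seed")
  rhdf5::H5Fclose(fid)
  invisible(path)
}
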