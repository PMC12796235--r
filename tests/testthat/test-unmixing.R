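test_that("frame_to_matrix arranges pixels x ascending wavelengths", {
  oa <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
  scan <- msopus_scan(us_images = array(0, c(2, 2, 2)),
                      us_timestamps = c(0.02, 0.06),
                      oa_images = oa, oa_timestamps = c(0.0, 0.04, 0.08),
                      oa_wavelengths = c(700, 710, 720))
  I <- frame_to_matrix(scan, 1)
  expect_identical(dim(I), c(4L, 3L))
  # pixel (1,1) row = its intensity at each wavelength
  expect_equal(I[1, ], c(oa[1, 1, 1], oa[1, 1, 2], oa[1, 1, 3]))
  # round trip to an image stack and back
  expect_equal(matrix_to_frame(I), oa)
  # wavelength columns follow ascending wavelength even when the frame does
  # not start at the lowest wavelength: frame 2 of a (700, 710) cycle covers
  # images (2, 3) at (710, 700) nm, so image 3 supplies the first column
  scan2 <- msopus_scan(us_images = array(0, c(2, 2, 2)),
                       us_timestamps = c(0.02, 0.06),
                       oa_images = oa, oa_timestamps = c(0.0, 0.04, 0.08),
                       oa_wavelengths = c(700, 710, 700))
  I2 <- frame_to_matrix(scan2, 2)
  expect_equal(I2[, 1], as.vector(oa[, , 3]))  # 700 nm first
  expect_equal(I2[, 2], as.vector(oa[, , 2]))
})

test_that("NNLS recovers exact nonnegative mixtures", {
  W <- withr::with_seed(1, matrix(runif(4 * 12, 0.2, 1), 4, 12))
  C0 <- withr::with_seed(2, matrix(runif(30 * 4), 30, 4))
  C0[C0 < 0.2] <- 0
  res <- nnls_unmix(C0 %*% W, W)
  expect_lt(max(abs(res$C - C0)), 1e-8)
  expect_lt(res$E, 1e-9)
  expect_true(all(res$C >= 0))
  # zero frame: zero coefficients (residual is undefined)
  suppressWarnings(zero <- nnls_unmix(matrix(0, 5, 12), W))
  expect_true(all(zero$C == 0))
  expect_identical(zero$E, NA_real_)
  # closed form: identity spectra
  one <- nnls_unmix(matrix(c(1, 2), 1), diag(2))
  expect_equal(as.vector(one$C), c(1, 2))
})

test_that("NNLS matches the Lawson-Hanson oracle on random problems", {
  for (seed in 1:6) {
    dat <- withr::with_seed(seed, list(
      W = matrix(rnorm(3 * 8), 3, 8),
      I = matrix(rnorm(10 * 8), 10, 8)))
    got <- nnls_unmix(dat$I, dat$W)$C
    want <- t(apply(dat$I, 1, function(y) pracma::lsqnonneg(t(dat$W), y)$x))
    expect_equal(got, want, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("NNLS rejects mismatched wavelength grids", {
  W <- chromophore_spectra(seq(700, 900, 10))
  I <- matrix(runif(4 * 21), 4, 21)
  attr(I, "wavelengths") <- seq(705, 905, 10)
  expect_error(nnls_unmix(I, W), class = "msopus_validation_error")
  expect_error(nnls_unmix(matrix(0, 2, 5), W),
               class = "msopus_validation_error")
})

test_that("the relative L2,1 residual matches its definition", {
  I <- matrix(c(3, 4), 1)
  expect_equal(unmix_residual(I, matrix(1), matrix(c(3, 4), 1)), 0)
  expect_equal(unmix_residual(I, matrix(0), matrix(c(3, 4), 1)), 1)
  # reconstruction [3, 0] of spectrum [3, 4]: ||[0,4]|| / ||[3,4]|| = 4/5
  expect_equal(unmix_residual(I, matrix(1), matrix(c(3, 0), 1)), 0.8)
  # scale invariance
  W <- withr::with_seed(3, matrix(runif(2 * 6), 2, 6))
  C <- withr::with_seed(4, matrix(runif(9 * 2), 9, 2))
  Im <- C %*% W + 0.05
  expect_equal(unmix_residual(7 * Im, 7 * C, W), unmix_residual(Im, C, W))
  expect_warning(e0 <- unmix_residual(matrix(0, 2, 3), matrix(0, 2, 1),
                                      matrix(0, 1, 3)), "zero-norm")
  expect_identical(e0, NA_real_)
})

test_that("NMF factorizes nonnegative data with monotone error", {
  I1 <- withr::with_seed(5, outer(runif(40, 0.1, 1), runif(12, 0.1, 1)))
  res <- nmf_blind_unmix(I1, k = 1, seed = 3)
  expect_lt(res$E, 1e-6)  # rank-1 data factorizes exactly
  expect_true(all(res$C >= 0) && all(res$W >= 0))
  # non-increasing relative to the problem scale (exact monotonicity is
  # meaningless once the error reaches numerical zero)
  expect_true(all(diff(res$err_trace) <= 1e-10 * sqrt(sum(I1^2))))
  expect_error(nmf_blind_unmix(I1, k = 13), class = "msopus_validation_error")
  expect_warning(nmf_blind_unmix(matrix(c(-1, 1, 2, 3), 2), k = 1, seed = 1),
                 "clipped")
})

test_that("NMF is deterministic under a fixed seed", {
  I1 <- withr::with_seed(6, matrix(runif(50 * 10), 50, 10))
  a <- nmf_blind_unmix(I1, k = 3, seed = 42)
  b <- nmf_blind_unmix(I1, k = 3, seed = 42)
  expect_identical(a$C, b$C)
  expect_identical(a$W, b$W)
})

test_that("blind NMF recovers two synthetic absorber spectra", {
  wl <- seq(700, 970, 10)
  W0 <- chromophore_spectra(wl, c("hb", "lipid"))
  maps <- withr::with_seed(7, {
    m1 <- matrix(0, 16, 16); m1[3:8, 3:8] <- runif(36, 0.5, 1)
    m2 <- matrix(0, 16, 16); m2[9:14, 9:14] <- runif(36, 0.5, 1)
    cbind(as.vector(m1), as.vector(m2))
  })
  I1 <- maps %*% W0
  res <- nmf_blind_unmix(I1, k = 2, seed = 11)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim_mat <- outer(1:2, 1:2, Vectorize(function(i, j)
    cosine(res$W[i, ], W0[j, ])))
  best <- max(sim_mat[1, 1] + sim_mat[2, 2], sim_mat[1, 2] + sim_mat[2, 1]) / 2
  expect_gte(best, 0.99)
  expect_lt(res$E, 0.01)
})

test_that("bundled spectra interpolate onto scan grids", {
  W <- chromophore_spectra(seq(700, 970, 10))
  expect_identical(rownames(W), c("hb", "hbo2", "water", "lipid"))
  expect_identical(ncol(W), 28L)
  expect_true(all(is.finite(W)) && all(W > 0))
  # linear interpolation between tabulated 5 nm knots
  W5 <- chromophore_spectra(c(700, 702.5, 705), "hb")
  expect_equal(unname(W5[1, 2]), unname(mean(W5[1, c(1, 3)])))
  expect_error(chromophore_spectra(c(500, 700)),
               class = "msopus_validation_error")
  expect_error(chromophore_spectra(800, "melanin"),
               class = "msopus_format_error")
})

test_that("unmixing results write to HDF5 with metadata", {
  W <- chromophore_spectra(seq(700, 900, 20))
  I <- withr::with_seed(8, matrix(runif(6 * 11), 6, 11))
  res <- nnls_unmix(I, W)
  path <- withr::local_tempfile(fileext = ".h5")
  write_unmix(res, path)
  expect_equal(as.vector(rhdf5::h5read(path, "C")), as.vector(res$C))
  attrs <- rhdf5::h5readAttributes(path, "/")
  expect_equal(as.double(attrs$E), res$E)
  expect_identical(as.character(attrs$method), "nnls")
})
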