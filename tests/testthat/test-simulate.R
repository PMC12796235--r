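test_that("config validation catches bad segment specs", {
  expect_error(sim_config(segments = list(list(type = "warp", duration = 1))),
               class = "msopus_config_error")
  expect_error(sim_config(segments = list(list(type = "drift", duration = 0,
                                               amplitude = 1))),
               class = "msopus_config_error")
  expect_error(sim_config(segments = list(list(type = "drift", duration = 1,
                                               amplitude = -2))),
               class = "msopus_config_error")
  expect_error(sim_config(segments = list()), class = "msopus_config_error")
})

test_that("trajectories follow the segment taxonomy", {
  still <- sim_config(segments = list(list(type = "stationary", duration = 5)))
  tr <- motion_trajectory(still, seq(0, 5, 0.5), seed = 1)
  expect_true(all(tr$dx == 0 & tr$dy == 0 & tr$theta == 0))

  drift <- sim_config(segments = list(list(type = "drift", duration = 2,
                                           amplitude = 10, direction = 0)))
  tr2 <- motion_trajectory(drift, c(0, 1, 2), seed = 1)
  expect_equal(tr2$dx, c(0, 5, 10))
  expect_equal(tr2$dy, c(0, 0, 0))

  rot <- sim_config(segments = list(list(type = "rotation", duration = 4,
                                         amplitude = 8)))
  tr3 <- motion_trajectory(rot, c(0, 2, 4), seed = 1)
  expect_equal(tr3$theta, c(0, 4, 8))

  # jerk: instantaneous step at segment start, then constant
  jerk <- sim_config(segments = list(
    list(type = "stationary", duration = 1),
    list(type = "jerk", duration = 1, amplitude = 3, direction = 0)))
  tr4 <- motion_trajectory(jerk, c(0.5, 1.2, 1.9), seed = 1)
  expect_equal(tr4$dx, c(0, 3, 3))

  # jitter: zero-mean displacement around a held pose, seeded
  jit <- sim_config(segments = list(list(type = "jitter", duration = 4,
                                         sigma = 0.5)))
  tj <- motion_trajectory(jit, seq(0.1, 3.9, 0.2), seed = 5)
  expect_gt(stats::sd(tj$dx), 0.2)
  expect_identical(tj, motion_trajectory(jit, seq(0.1, 3.9, 0.2), seed = 5))
})

test_that("pose paths are continuous across non-jerk boundaries", {
  cfg <- sim_config(segments = list(
    list(type = "drift", duration = 2, amplitude = 6, direction = 30),
    list(type = "stationary", duration = 1),
    list(type = "rotation", duration = 2, amplitude = 10)))
  t <- seq(0, 5, 0.01)
  tr <- motion_trajectory(cfg, t, seed = 1)
  step <- sqrt(diff(tr$dx)^2 + diff(tr$dy)^2) + abs(diff(tr$theta))
  expect_lt(max(step), 0.1)  # no jumps anywhere
})

test_that("US rendering is pose-deterministic and shift-equivariant", {
  cfg <- sim_config(us_size = c(40, 40), noise_us = 0)
  scat <- withr::with_seed(3, data.frame(
    x = runif(800, 1 - cfg$scatter_margin, 40 + cfg$scatter_margin),
    y = runif(800, 1 - cfg$scatter_margin, 40 + cfg$scatter_margin),
    amp = rnorm(800)))
  a <- render_us(scat, c(0, 0, 0), cfg)
  b <- render_us(scat, c(0, 0, 0), cfg)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  # integer translation shifts the image content
  shifted <- render_us(scat, c(3, 0, 0), cfg)
  expect_equal(shifted[5:36, 9:36], a[5:36, 6:33], tolerance = 1e-12)
})

test_that("OA rendering follows the linear spectral model", {
  wl <- c(700, 800)
  spectra <- matrix(c(2, 1), 1, 2, dimnames = list("hb", NULL))
  attr(spectra, "wavelengths") <- wl
  phantom <- list(absorbers = list(list(name = "hb", center = c(10, 10),
                                        radius = 5, concentration = 1)),
                  spectra = spectra)
  cfg <- sim_config(oa_size = c(24, 24), wavelengths = wl, fluence_mu = 0,
                    noise_oa = 0)
  i700 <- render_oa(phantom, c(0, 0, 0), 700, cfg)
  i800 <- render_oa(phantom, c(0, 0, 0), 800, cfg)
  inside <- i800 > 0
  expect_true(any(inside))
  expect_equal(i700[inside], 2 * i800[inside])
  # zero concentration -> zero image
  phantom0 <- phantom
  phantom0$absorbers[[1]]$concentration <- 0
  expect_true(all(render_oa(phantom0, c(0, 0, 0), 700, cfg) == 0))
  expect_error(render_oa(phantom, c(0, 0, 0), 750, cfg),
               class = "msopus_config_error")
})

test_that("stationary frames unmix at the noise floor", {
  cfg <- sim_config(us_size = c(24, 24), oa_size = c(24, 24),
                    wavelengths = seq(700, 970, 30),
                    segments = list(list(type = "stationary", duration = 2)),
                    noise_us = 0, noise_oa = 0)
  sim <- simulate_scan(cfg, seed = 9)
  I <- frame_to_matrix(sim$scan, 1)
  res <- nnls_unmix(I, sim$truth$spectra)
  expect_lt(res$E, 1e-6)  # float32 storage bounds the residual
  # the renderer itself is exact in double precision
  phantom <- list(absorbers = default_phantom(cfg$wavelengths, c(24, 24))$absorbers,
                  spectra = sim$truth$spectra)
  stack <- vapply(cfg$wavelengths, function(w)
    render_oa(phantom, c(0, 0, 0), w, cfg), matrix(0, 24, 24))
  I2 <- matrix(stack, ncol = length(cfg$wavelengths))
  expect_lt(nnls_unmix(I2, sim$truth$spectra)$E, 1e-9)
})

test_that("simulated scans honor rates, cycling and the scan invariants", {
  cfg <- sim_config(us_size = c(16, 16), oa_size = c(12, 12),
                    wavelengths = seq(700, 790, 30),
                    segments = list(list(type = "stationary", duration = 4)))
  sim <- simulate_scan(cfg, seed = 1)
  expect_identical(dim(sim$scan$us_images)[3], 25L)  # 4 s at 6.25 Hz
  expect_identical(dim(sim$scan$oa_images)[3], 100L)
  nl <- length(cfg$wavelengths)
  expect_identical(sim$scan$oa_wavelengths[seq_len(nl)],
                   sim$scan$oa_wavelengths[nl + seq_len(nl)])
  expect_silent(validate_scan(sim$scan))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(us_size = c(16, 16), oa_size = c(12, 12),
                    wavelengths = seq(700, 790, 30),
                    segments = list(list(type = "jitter", duration = 3,
                                         sigma = 0.5)))
  a <- simulate_scan(cfg, seed = 31)
  b <- simulate_scan(cfg, seed = 31)
  expect_identical(a$scan, b$scan)
  expect_identical(a$truth$pose_oa, b$truth$pose_oa)
  c2 <- simulate_scan(cfg, seed = 32)
  expect_false(identical(a$scan$us_images, c2$scan$us_images))
})

test_that("ground-truth intervals line up with the stationary segments", {
  sim <- small_sim()  # stationary 0-2 s, drift 2-5 s, stationary 5-7 s
  expect_equal(unname(sim$truth$stationary_time_intervals),
               cbind(c(0, 5), c(2, 7)))
  t_us <- sim$scan$us_timestamps
  for (r in 1:2) {
    iv <- sim$truth$stationary_us_intervals[r, ]
    expect_true(all(t_us[iv[1]:iv[2]] >= sim$truth$stationary_time_intervals[r, 1] - 1e-9))
    expect_true(all(t_us[iv[1]:iv[2]] <= sim$truth$stationary_time_intervals[r, 2] + 1e-9))
  }
  # every truth-stationary frame's US images sit inside one segment
  fr <- ms_frames(sim$scan)
  for (r in seq_len(nrow(sim$truth$stationary_frame_intervals))) {
    iv <- sim$truth$stationary_frame_intervals[r, ]
    for (k in iv[1]:iv[2]) {
      ts <- t_us[fr[[k]]$s]
      expect_true(any(ts[1] >= sim$truth$stationary_time_intervals[, 1] - 1e-9 &
                      ts[length(ts)] <= sim$truth$stationary_time_intervals[, 2] + 1e-9))
    }
  }
})

test_that("truth JSON round trips the intervals and poses", {
  sim <- small_sim()
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(unname(back$stationary_frame_intervals),
               unname(sim$truth$stationary_frame_intervals))
  expect_equal(back$pose_us$dx, sim$truth$pose_us$dx)
  expect_identical(back$seed, sim$truth$seed)
})

test_that("corpus configurations draw from the documented taxonomy", {
  cc <- corpus_configs(4, seed = 3)
  expect_length(cc, 4L)
  expect_identical(cc, corpus_configs(4, seed = 3))  # deterministic
  for (ce in cc) {
    types <- vapply(ce$config$segments, `[[`, character(1), "type")
    n_stat <- sum(types == "stationary")
    expect_true(n_stat %in% 2:3)
    durs <- vapply(ce$config$segments, `[[`, numeric(1), "duration")
    expect_true(all(durs[types == "stationary"] >= 1.8 &
                    durs[types == "stationary"] <= 2.4))
    expect_false(types[1] == "stationary" || types[length(types)] == "stationary")
  }
})
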