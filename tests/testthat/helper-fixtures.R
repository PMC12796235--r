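# Fixture builders shared across test files.

# A scan with scalar (1x1) US images: the value vector IS the image sequence.
scalar_us_scan <- function(us_values, t_us, t_oa, wl_cycle) {
  n_oa <- length(t_oa)
  msopus_scan(
    us_images = array(us_values, c(1, 1, length(us_values))),
    us_timestamps = t_us,
    oa_images = array(0, c(2, 2, n_oa)),
    oa_timestamps = t_oa,
    oa_wavelengths = rep_len(wl_cycle, n_oa))
}

# Random small scan for property tests: n_us US images of size img x img,
# n_lambda-wavelength preset, timestamps interleaved at fixed rates.
random_scan <- function(n_us, n_oa, n_lambda, img = 8L, seed = 1L,
                        f_us = 6.25, f_oa = 25) {
  withr::with_seed(seed, {
    msopus_scan(
      us_images = array(runif(img * img * n_us), c(img, img, n_us)),
      us_timestamps = (seq_len(n_us) - 0.5) / f_us,
      oa_images = array(runif(4 * 4 * n_oa), c(4, 4, n_oa)),
      oa_timestamps = (seq_len(n_oa) - 0.5) / f_oa,
      oa_wavelengths = rep_len(seq(700, by = 10, length.out = n_lambda), n_oa))
  })
}

# Small simulated scan reused by several files (cached per test run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        us_size = c(48, 48), oa_size = c(24, 24),
        wavelengths = seq(700, 970, by = 30),
        segments = list(
          list(type = "stationary", duration = 2),
          list(type = "drift", duration = 3, amplitude = 9, direction = 20),
          list(type = "stationary", duration = 2)))
      cache <<- simulate_scan(cfg, seed = 7L)
    }
    cache
  }
})
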