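#' Simulator configuration for synthetic MS-OPUS scans
#'
#' Defines the acquisition geometry, the piecewise motion of the probe
#' relative to the tissue, and the spectral phantom of a simulated scan.
#' Defaults reproduce the validated acquisition preset: a 700-970 nm
#' wavelength sweep in 10 nm steps (28 wavelengths), 25 Hz OA and 6.25 Hz US
#' acquisition.
#'
#' @param us_size,oa_size image dimensions `c(H, W)` in pixels.
#' @param wavelengths ascending OA wavelength preset in nm.
#' @param f_oa,f_us acquisition rates in Hz.
#' @param segments list of motion segments executed in order; each a list
#'   with `type` (one of `"stationary"`, `"drift"`, `"rotation"`, `"jitter"`,
#'   `"jerk"`), `duration` (s), and type-specific fields: `amplitude`
#'   (total translation in px for drift/jerk, total rotation in degrees for
#'   rotation), `sigma` (per-timestamp jitter displacement SD in px),
#'   `direction` (translation direction in degrees; `NULL` draws one per
#'   segment from the seed).  The pose path is continuous across segment
#'   boundaries except at jerks.
#' @param phantom absorber layout, see [default_phantom()]; `NULL` uses the
#'   default built on `wavelengths`.
#' @param noise_us,noise_oa additive Gaussian noise SD per stream (image
#'   intensity units).
#' @param psf_sigma US point-spread Gaussian SD in px.
#' @param n_scatterers number of US speckle scatterers.
#' @param scatter_margin margin (px) around the field of view populated with
#'   scatterers so that motion does not empty the image borders.
#' @param fluence_mu exponential fluence decay constant over the image depth
#'   (0 disables).
#' @return a validated list of class `msopus_sim_config`.
#' @export
sim_config <- function(us_size = c(64, 64),
                       oa_size = c(64, 64),
                       wavelengths = seq(700, 970, by = 10),
                       f_oa = 25,
                       f_us = 6.25,
                       segments = list(
                         list(type = "stationary", duration = 3),
                         list(type = "drift", duration = 5, amplitude = 10),
                         list(type = "stationary", duration = 3),
                         list(type = "jitter", duration = 5, sigma = 0.75),
                         list(type = "stationary", duration = 3)),
                       phantom = NULL,
                       noise_us = 0.01,
                       noise_oa = 0.005,
                       psf_sigma = 1.2,
                       n_scatterers = 1500,
                       scatter_margin = 16,
                       fluence_mu = 1) {
  cfg <- structure(list(us_size = as.integer(us_size),
                        oa_size = as.integer(oa_size),
                        wavelengths = as.double(wavelengths),
                        f_oa = f_oa, f_us = f_us,
                        segments = segments,
                        phantom = phantom,
                        noise_us = noise_us, noise_oa = noise_oa,
                        psf_sigma = psf_sigma,
                        n_scatterers = as.integer(n_scatterers),
                        scatter_margin = as.integer(scatter_margin),
                        fluence_mu = fluence_mu),
                   class = "msopus_sim_config")
  validate_sim_config(cfg)
  cfg
}

segment_types <- c("stationary", "drift", "rotation", "jitter", "jerk")

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$us_size) == 2L, length(cfg$oa_size) == 2L,
            cfg$f_oa > 0, cfg$f_us > 0, length(cfg$wavelengths) >= 1L,
            !is.unsorted(cfg$wavelengths, strictly = TRUE),
            cfg$noise_us >= 0, cfg$noise_oa >= 0, cfg$psf_sigma > 0,
            cfg$n_scatterers >= 1L, cfg$scatter_margin >= 0L,
            cfg$fluence_mu >= 0)
  if (!length(cfg$segments))
    stop_msopus("at least one motion segment is required",
                class = "msopus_config_error")
  for (sg in cfg$segments) {
    if (is.null(sg$type) || !sg$type %in% segment_types)
      stop_msopus("unknown segment type: %s", toString(sg$type %||% "<missing>"),
                  class = "msopus_config_error")
    if (is.null(sg$duration) || sg$duration <= 0)
      stop_msopus("segment durations must be positive",
                  class = "msopus_config_error")
    if (!is.null(sg$amplitude) && sg$amplitude < 0)
      stop_msopus("segment amplitudes must be >= 0",
                  class = "msopus_config_error")
    if (!is.null(sg$sigma) && sg$sigma < 0)
      stop_msopus("jitter sigma must be >= 0", class = "msopus_config_error")
  }
  invisible(cfg)
}

scan_duration <- function(cfg) {
  sum(vapply(cfg$segments, `[[`, numeric(1), "duration"))
}

#' Default spectral phantom
#'
#' Three absorber disks (deoxyhemoglobin, oxyhemoglobin, lipid) on a faint
#' water background, with spectra interpolated from the bundled synthetic
#' chromophore table.  Every pixel's spectrum is, by construction, a
#' non-negative combination of the component spectra, so stationary frames
#' unmix with a residual at the noise level.
#'
#' @param wavelengths OA wavelength grid (nm).
#' @param oa_size OA image dimensions `c(H, W)`.
#' @return list with `absorbers` (each: `name`, `center` in `c(x, y)` px,
#'   `radius` px, `concentration`) and `spectra` (component x wavelength
#'   matrix).
#' @export
default_phantom <- function(wavelengths, oa_size = c(64, 64)) {
  h <- oa_size[1]; w <- oa_size[2]
  absorbers <- list(
    list(name = "hb",    center = c(0.35 * w, 0.40 * h), radius = 0.12 * h,
         concentration = 1.0),
    list(name = "hbo2",  center = c(0.62 * w, 0.55 * h), radius = 0.15 * h,
         concentration = 0.8),
    list(name = "lipid", center = c(0.50 * w, 0.75 * h), radius = 0.10 * h,
         concentration = 1.2),
    list(name = "water", center = c(0.50 * w, 0.50 * h), radius = 0.90 * max(h, w),
         concentration = 0.15))
  list(absorbers = absorbers,
       spectra = chromophore_spectra(wavelengths,
                                     c("hb", "hbo2", "lipid", "water")))
}

#' Piecewise rigid pose trajectory
#'
#' Evaluates the configured motion segments at the given (sorted) timestamps.
#' Stationary segments hold the pose; drift translates at constant velocity;
#' rotation ramps the angle at a constant rate; jitter adds zero-mean
#' Gaussian per-timestamp displacement around a held pose; jerk applies an
#' instantaneous step at the segment start.  The path is continuous across
#' boundaries except at jerks.
#'
#' @param cfg an `msopus_sim_config`.
#' @param times sorted timestamps (s) in `[0, scan duration]`.
#' @param seed integer seed driving segment directions and jitter draws.
#' @return data.frame with columns `time`, `dx`, `dy` (px), `theta` (deg).
#' @export
motion_trajectory <- function(cfg, times, seed = 1L) {
  validate_sim_config(cfg)
  stopifnot(!is.unsorted(times))
  segs <- cfg$segments
  n_seg <- length(segs)
  durs <- vapply(segs, `[[`, numeric(1), "duration")
  t0 <- cumsum(c(0, durs[-n_seg]))
  seeds <- substream_seeds(seed, 2L)
  dir_deg <- with_seed(seeds[1], vapply(segs, function(sg)
    as.double(sg$direction %||% stats::runif(1, 0, 360)), numeric(1)))
  # sequential start/end poses (dx, dy, theta)
  start_pose <- matrix(0, n_seg, 3)
  pose <- c(0, 0, 0)
  for (i in seq_len(n_seg)) {
    sg <- segs[[i]]
    if (sg$type == "jerk") {
      dir <- dir_deg[i] * pi / 180
      pose <- pose + c(sg$amplitude * cos(dir), sg$amplitude * sin(dir), 0)
    }
    start_pose[i, ] <- pose
    if (sg$type == "drift") {
      dir <- dir_deg[i] * pi / 180
      pose <- pose + c(sg$amplitude * cos(dir), sg$amplitude * sin(dir), 0)
    } else if (sg$type == "rotation") {
      pose <- pose + c(0, 0, sg$amplitude)
    }
  }
  si <- pmax(1L, pmin(findInterval(times, t0), n_seg))
  out <- matrix(0, length(times), 3)
  for (i in seq_len(n_seg)) {
    rows <- which(si == i)
    if (!length(rows)) next
    sg <- segs[[i]]
    tau <- times[rows] - t0[i]
    base <- matrix(start_pose[i, ], length(rows), 3, byrow = TRUE)
    if (sg$type == "drift") {
      dir <- dir_deg[i] * pi / 180
      base[, 1] <- base[, 1] + sg$amplitude * cos(dir) * tau / durs[i]
      base[, 2] <- base[, 2] + sg$amplitude * sin(dir) * tau / durs[i]
    } else if (sg$type == "rotation") {
      base[, 3] <- base[, 3] + sg$amplitude * tau / durs[i]
    }
    out[rows, ] <- base
  }
  jit_rows <- which(vapply(segs, `[[`, character(1), "type")[si] == "jitter")
  if (length(jit_rows)) {
    draws <- with_seed(seeds[2], matrix(stats::rnorm(2L * length(jit_rows)),
                                        ncol = 2))
    sig <- vapply(segs, function(sg) as.double(sg$sigma %||% 0), numeric(1))
    out[jit_rows, 1] <- out[jit_rows, 1] + sig[si[jit_rows]] * draws[, 1]
    out[jit_rows, 2] <- out[jit_rows, 2] + sig[si[jit_rows]] * draws[, 2]
  }
  data.frame(time = times, dx = out[, 1], dy = out[, 2], theta = out[, 3])
}

# Forward rigid transform of scene points: rotate by theta (deg) about the
# image center, then translate by (dx, dy).  x = column, y = row.
rigid_forward <- function(x, y, pose, center) {
  th <- pose[3] * pi / 180
  xc <- x - center[1]; yc <- y - center[2]
  list(x = cos(th) * xc - sin(th) * yc + center[1] + pose[1],
       y = sin(th) * xc + cos(th) * yc + center[2] + pose[2])
}

# Inverse transform of image points back into scene coordinates.
rigid_inverse <- function(x, y, pose, center) {
  th <- pose[3] * pi / 180
  xc <- x - center[1] - pose[1]
  yc <- y - center[2] - pose[2]
  list(x = cos(th) * xc + sin(th) * yc + center[1],
       y = -sin(th) * xc + cos(th) * yc + center[2])
}

# Bilinear splat of weighted points onto an H x W grid (base-R rowsum
# aggregation; points outside the grid are dropped).
splat_bilinear <- function(x, y, amp, h, w) {
  ix <- floor(x); iy <- floor(y)
  fx <- x - ix; fy <- y - iy
  px <- c(ix, ix + 1, ix, ix + 1)
  py <- c(iy, iy, iy + 1, iy + 1)
  wt <- c(amp * (1 - fx) * (1 - fy), amp * fx * (1 - fy),
          amp * (1 - fx) * fy, amp * fx * fy)
  ok <- px >= 1 & px <= w & py >= 1 & py <= h
  out <- numeric(h * w)
  if (any(ok)) {
    idx <- (px[ok] - 1) * h + py[ok]
    agg <- rowsum(wt[ok], idx)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  matrix(out, h, w)
}

#' Render one synthetic US speckle image
#'
#' A fixed scatterer field is rigid-transformed by the pose, splatted
#' bilinearly onto a padded canvas, convolved with a Gaussian point-spread
#' kernel, and envelope-detected (absolute value).  Identical poses give
#' identical images; an integer-pixel translation of the pose shifts the
#' image away from the borders.  Noise is not added here; the scan simulator
#' adds seeded Gaussian noise and clips at zero.
#'
#' @param scatterers data.frame with `x`, `y` (scene coordinates, px) and
#'   `amp`.
#' @param pose numeric `c(dx, dy, theta_deg)`.
#' @param cfg an `msopus_sim_config` (uses `us_size`, `psf_sigma`,
#'   `scatter_margin`).
#' @return nonnegative `H x W` matrix.
#' @export
render_us <- function(scatterers, pose, cfg) {
  h <- cfg$us_size[1]; w <- cfg$us_size[2]
  m <- cfg$scatter_margin
  center <- c((w + 1) / 2, (h + 1) / 2)
  p <- rigid_forward(scatterers$x, scatterers$y, pose, center)
  canvas <- splat_bilinear(p$x + m, p$y + m, scatterers$amp, h + 2 * m, w + 2 * m)
  ksz <- 2L * ceiling(3 * cfg$psf_sigma) + 1L
  g <- gaussian_kernel(ksz, cfg$psf_sigma)
  Br <- conv_band_same(h + 2 * m, g)
  Bc <- conv_band_same(w + 2 * m, g)
  rf <- Br %*% canvas %*% t(Bc)
  abs(rf)[(m + 1):(m + h), (m + 1):(m + w)]
}

#' Render one synthetic single-wavelength OA image
#'
#' Absorber disks (1 px smoothed edges) are evaluated analytically at the
#' inverse-transformed pixel coordinates, weighted by the component spectrum
#' at the requested wavelength, summed, and attenuated by an exponential
#' fluence decay over depth.  The pixel spectra therefore follow the linear
#' mixing model exactly, so stationary frames unmix with a residual at the
#' noise level.
#'
#' @param phantom see [default_phantom()].
#' @param pose numeric `c(dx, dy, theta_deg)`.
#' @param wavelength nm; must be on the phantom's wavelength grid.
#' @param cfg an `msopus_sim_config` (uses `oa_size`, `fluence_mu`).
#' @return `H x W` matrix (noise-free).
#' @export
render_oa <- function(phantom, pose, wavelength, cfg) {
  h <- cfg$oa_size[1]; w <- cfg$oa_size[2]
  wl <- attr(phantom$spectra, "wavelengths") %||% cfg$wavelengths
  li <- which(abs(wl - wavelength) < 1e-9)
  if (length(li) != 1L)
    stop_msopus("wavelength %g nm not on the phantom grid", wavelength,
                class = "msopus_config_error")
  center <- c((w + 1) / 2, (h + 1) / 2)
  px <- matrix(seq_len(w), h, w, byrow = TRUE)
  py <- matrix(seq_len(h), h, w)
  q <- rigid_inverse(px, py, pose, center)
  img <- matrix(0, h, w)
  for (ab in phantom$absorbers) {
    if (!ab$name %in% rownames(phantom$spectra))
      stop_msopus("unknown absorber name: %s", ab$name,
                  class = "msopus_config_error")
    dist <- sqrt((q$x - ab$center[1])^2 + (q$y - ab$center[2])^2)
    memb <- clamp(ab$radius - dist + 0.5, 0, 1)
    img <- img + ab$concentration * phantom$spectra[ab$name, li] * memb
  }
  if (cfg$fluence_mu > 0)
    img <- img * exp(-cfg$fluence_mu * (py - 1) / max(1, h - 1))
  img
}

#' Simulate a complete MS-OPUS scan with ground truth
#'
#' Builds interleaved timestamp grids at the configured rates, samples one
#' shared pose trajectory at both streams' timestamps, renders speckled US
#' and spectrally structured OA images along it, adds seeded Gaussian noise,
#' and returns the scan together with the simulation truth.  All randomness
#' derives from `seed` through independent substreams (trajectory,
#' scatterers, US noise, OA noise), so equal seeds give bit-identical scans.
#'
#' @param cfg an `msopus_sim_config`.
#' @param seed integer root seed.
#' @return list of class `msopus_sim` with elements `scan` (an
#'   `msopus_scan`) and `truth`: `pose_us`/`pose_oa` (per-timestamp pose),
#'   `stationary_time_intervals` (seconds, exactly the stationary segments),
#'   `stationary_us_intervals` (US images acquired inside them) and
#'   `stationary_frame_intervals` (frames whose US images all fall inside one
#'   stationary segment -- motion is only observable at US timestamps;
#'   inclusive index ranges),
#'   `concentration_maps` (zero-pose absorber maps, `H x W x k`), `spectra`,
#'   `fluence_mu`, `seed`.
#' @export
simulate_scan <- function(cfg, seed = 1L) {
  validate_sim_config(cfg)
  phantom <- cfg$phantom %||% default_phantom(cfg$wavelengths, cfg$oa_size)
  dur <- scan_duration(cfg)
  seeds <- substream_seeds(seed, 4L)
  n_us <- floor(dur * cfg$f_us)
  n_oa <- floor(dur * cfg$f_oa)
  if (n_us < 1L || n_oa < length(cfg$wavelengths))
    stop_msopus("scan too short for the configured rates/preset",
                class = "msopus_config_error")
  t_us <- (seq_len(n_us) - 0.5) / cfg$f_us
  t_oa <- (seq_len(n_oa) - 0.5) / cfg$f_oa
  all_t <- c(t_us, t_oa)
  ord <- order(all_t)
  traj <- motion_trajectory(cfg, all_t[ord], seed = seeds[1])
  poses <- matrix(0, length(all_t), 3)
  poses[ord, ] <- as.matrix(traj[, c("dx", "dy", "theta")])
  pose_us <- poses[seq_len(n_us), , drop = FALSE]
  pose_oa <- poses[n_us + seq_len(n_oa), , drop = FALSE]

  scatterers <- with_seed(seeds[2], data.frame(
    x = stats::runif(cfg$n_scatterers, 1 - cfg$scatter_margin,
                     cfg$us_size[2] + cfg$scatter_margin),
    y = stats::runif(cfg$n_scatterers, 1 - cfg$scatter_margin,
                     cfg$us_size[1] + cfg$scatter_margin),
    amp = stats::rnorm(cfg$n_scatterers)))

  us <- array(0, c(cfg$us_size[1], cfg$us_size[2], n_us))
  with_seed(seeds[3], for (j in seq_len(n_us)) {
    img <- render_us(scatterers, pose_us[j, ], cfg)
    if (cfg$noise_us > 0)
      img <- pmax(img + matrix(stats::rnorm(length(img), sd = cfg$noise_us),
                               nrow(img)), 0)
    us[, , j] <- img
  })

  n_lambda <- length(cfg$wavelengths)
  oa_wl <- cfg$wavelengths[((seq_len(n_oa) - 1L) %% n_lambda) + 1L]
  oa <- array(0, c(cfg$oa_size[1], cfg$oa_size[2], n_oa))
  with_seed(seeds[4], for (k in seq_len(n_oa)) {
    img <- render_oa(phantom, pose_oa[k, ], oa_wl[k], cfg)
    if (cfg$noise_oa > 0)
      img <- img + matrix(stats::rnorm(length(img), sd = cfg$noise_oa), nrow(img))
    oa[, , k] <- img
  })

  scan <- msopus_scan(us_images = snap_float32(us),
                      us_timestamps = t_us,
                      oa_images = snap_float32(oa),
                      oa_timestamps = t_oa,
                      oa_wavelengths = oa_wl,
                      meta = list(scan_id = sprintf("sim-seed%d", seed),
                                  f_us_hz = cfg$f_us, f_oa_hz = cfg$f_oa))

  durs <- vapply(cfg$segments, `[[`, numeric(1), "duration")
  types <- vapply(cfg$segments, `[[`, character(1), "type")
  t0 <- cumsum(c(0, durs[-length(durs)]))
  t1 <- t0 + durs
  stat <- types == "stationary"
  stat_iv <- cbind(start = t0[stat], end = t1[stat])
  us_mask <- rep(FALSE, n_us)
  frame_mask <- rep(FALSE, max(0L, n_oa - n_lambda + 1L))
  # Probe motion is only observable at US timestamps, so a frame counts as
  # stationary when all of its (at least two) corresponding US images were
  # acquired inside one stationary segment, regardless of how far the OA
  # span protrudes -- the analogue of annotators labelling the US video.
  if (length(frame_mask)) {
    k <- seq_along(frame_mask)
    s_first <- findInterval(t_oa[k], t_us, left.open = TRUE) + 1L
    s_last <- findInterval(t_oa[k + n_lambda - 1L], t_us)
    has_us <- s_last - s_first >= 1L & s_first <= n_us & s_last >= 1L
  }
  eps <- 1e-9  # timestamps can land exactly on accumulated segment boundaries
  for (r in seq_len(nrow(stat_iv))) {
    us_mask <- us_mask |
      (t_us >= stat_iv[r, 1] - eps & t_us <= stat_iv[r, 2] + eps)
    if (length(frame_mask)) {
      frame_mask <- frame_mask |
        (has_us &
           t_us[pmax(1L, pmin(s_first, n_us))] >= stat_iv[r, 1] - eps &
           t_us[pmax(1L, pmin(s_last, n_us))] <= stat_iv[r, 2] + eps)
    }
  }
  maps <- vapply(phantom$absorbers, function(ab) {
    zero_cfg <- cfg
    zero_cfg$fluence_mu <- 0
    sp <- phantom
    sp$absorbers <- list(ab)
    render_oa(sp, c(0, 0, 0), cfg$wavelengths[1], zero_cfg) /
      phantom$spectra[ab$name, 1]
  }, matrix(0, cfg$oa_size[1], cfg$oa_size[2]))

  truth <- list(pose_us = data.frame(time = t_us, dx = pose_us[, 1],
                                     dy = pose_us[, 2], theta = pose_us[, 3]),
                pose_oa = data.frame(time = t_oa, dx = pose_oa[, 1],
                                     dy = pose_oa[, 2], theta = pose_oa[, 3]),
                stationary_time_intervals = stat_iv,
                stationary_us_intervals = as.matrix(events_from_mask(us_mask)),
                stationary_frame_intervals = as.matrix(events_from_mask(frame_mask)),
                concentration_maps = maps,
                spectra = phantom$spectra,
                fluence_mu = cfg$fluence_mu,
                seed = as.integer(seed))
  structure(list(scan = scan, truth = truth), class = "msopus_sim")
}

#' Study-corpus scan configurations
#'
#' The default synthetic validation corpus: `n_scans` scans at the standard
#' preset, each with 2-3 stationary holds of 1.8-2.4 s (just long enough for
#' 1-3 complete MS frames, the clinically minimal hold) separated by 7-10 s
#' moving blocks whose types are drawn from drift (6-12 px total), jitter
#' (sigma 0.75 px per timestamp), jerky step trains (1.5-4 px steps every
#' ~0.7 s, flanked by brief jitter) and rotation (10-20 degrees total).  Holds
#' are kept shorter than the default minimum peak separation so each true
#' event admits at most one selected minimum, and every moving block moves
#' throughout its span at the US sampling rate, keeping the segment-derived
#' ground truth observable.  Configurations are lightweight; simulate each
#' with [simulate_scan()].
#'
#' @param n_scans number of scans (default 10).
#' @param seed root seed; per-scan seeds are derived from it.
#' @return list of `n_scans` elements, each `list(config, seed)`.
#' @export
corpus_configs <- function(n_scans = 10L, seed = 1L) {
  with_seed(seed, {
    scan_seeds <- sample.int(.Machine$integer.max - 1L, n_scans)
    lapply(seq_len(n_scans), function(i) {
      n_stat <- sample(2:3, 1)
      segs <- list()
      # A moving block spans one U(7, 10) s interval.  Jerky motion is a
      # train of short step segments flanked by brief jitter: the pose is
      # constant between steps, so without the guards the pauses at the block
      # edges would merge with an adjacent stationary segment into a longer
      # true stillness than the ground-truth labels admit, and steps recur
      # faster than one frame span so every jerk-block frame contains motion.
      moving_block <- function() {
        type <- sample(c("drift", "jitter", "jerk", "rotation"), 1)
        dur <- stats::runif(1, 7, 10)
        if (type == "jerk") {
          guard <- list(type = "jitter", duration = 0.5, sigma = 0.75)
          inner <- dur - 1
          n_steps <- max(2L, round(inner / 0.7))
          return(c(list(guard),
                   lapply(seq_len(n_steps), function(i)
                     list(type = "jerk", duration = inner / n_steps,
                          amplitude = stats::runif(1, 1.5, 4))),
                   list(guard)))
        }
        sg <- list(type = type, duration = dur)
        if (type == "drift") sg$amplitude <- stats::runif(1, 6, 12)
        if (type == "rotation") sg$amplitude <- stats::runif(1, 10, 20)
        if (type == "jitter") sg$sigma <- 0.75
        list(sg)
      }
      for (j in seq_len(n_stat)) {
        segs <- c(segs, moving_block())
        segs[[length(segs) + 1L]] <- list(type = "stationary",
                                          duration = stats::runif(1, 1.8, 2.4))
      }
      segs <- c(segs, moving_block())
      list(config = sim_config(segments = segs), seed = scan_seeds[i])
    })
  })
}

#' Read and write simulation ground truth as JSON
#'
#' Serializes the per-timestamp pose and the stationary intervals (the large
#' concentration maps are omitted; regenerate them from the config).
#'
#' @param truth the `truth` element of an [simulate_scan()] result.
#' @param path JSON file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the truth
#'   list (without maps/spectra).
#' @export
write_truth <- function(truth, path) {
  obj <- list(stationary_us_intervals =
                unname(apply(truth$stationary_us_intervals, 1, as.integer,
                             simplify = FALSE)),
              stationary_frame_intervals =
                unname(apply(truth$stationary_frame_intervals, 1, as.integer,
                             simplify = FALSE)),
              stationary_time_intervals =
                unname(apply(truth$stationary_time_intervals, 1, as.double,
                             simplify = FALSE)),
              pose_us = truth$pose_us,
              pose_oa = truth$pose_oa,
              seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv <- function(x) {
    m <- if (is.matrix(x)) x
         else if (is.list(x)) do.call(rbind, x)
         else matrix(unlist(x), ncol = 2, byrow = TRUE)
    if (is.null(m)) m <- matrix(integer(0), ncol = 2)
    colnames(m) <- c("start", "end")
    m
  }
  list(stationary_us_intervals = iv(obj$stationary_us_intervals),
       stationary_frame_intervals = iv(obj$stationary_frame_intervals),
       stationary_time_intervals = iv(obj$stationary_time_intervals),
       pose_us = as.data.frame(obj$pose_us),
       pose_oa = as.data.frame(obj$pose_oa),
       seed = obj$seed)
}
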