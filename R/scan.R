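#' Construct an MS-OPUS scan object
#'
#' An MS-OPUS acquisition interleaves two timestamped image streams recorded
#' with one handheld probe: pulse-echo ultrasound (US) images and
#' single-wavelength optoacoustic (OA) images whose illumination wavelength
#' cycles through a fixed preset.  All indices in this package are 1-based,
#' matching the usual mathematical notation for the streams.
#'
#' @param us_images numeric array `H x W x N_US` of US images.
#' @param us_timestamps strictly increasing acquisition times (seconds),
#'   length `N_US`.
#' @param oa_images numeric array `H' x W' x N_OA` of single-wavelength OA
#'   images.
#' @param oa_timestamps strictly increasing acquisition times (seconds),
#'   length `N_OA`.
#' @param oa_wavelengths illumination wavelength (nm) of each OA image; must
#'   cycle with period equal to the number of distinct wavelengths.
#' @param meta list of free-form metadata; `scan_id`, `f_us_hz`, `f_oa_hz`
#'   are written to file headers when present.
#' @return An object of class `msopus_scan`: a list with the fields above
#'   plus `wavelengths`, the ascending wavelength preset.
#' @seealso [load_scan()], [save_scan()], [ms_frames()]
#' @export
msopus_scan <- function(us_images, us_timestamps, oa_images, oa_timestamps,
                        oa_wavelengths, meta = list()) {
  scan <- structure(
    list(us_images = us_images,
         us_timestamps = as.double(us_timestamps),
         oa_images = oa_images,
         oa_timestamps = as.double(oa_timestamps),
         oa_wavelengths = as.double(oa_wavelengths),
         wavelengths = sort(unique(as.double(oa_wavelengths))),
         meta = meta),
    class = "msopus_scan")
  validate_scan(scan)
  scan
}

#' Validate the invariants of an MS-OPUS scan
#'
#' Checks strict timestamp monotonicity, consistent image shapes within each
#' stream, and periodic wavelength cycling.
#' @param scan an `msopus_scan`.
#' @return `scan`, invisibly unchanged, or an error of class
#'   `msopus_validation_error`.
#' @export
validate_scan <- function(scan) {
  us <- scan$us_images; oa <- scan$oa_images
  if (length(dim(us)) != 3L || length(dim(oa)) != 3L)
    stop_msopus("us_images and oa_images must be 3-D arrays (H x W x N)",
                class = "msopus_validation_error")
  n_us <- dim(us)[3]; n_oa <- dim(oa)[3]
  if (length(scan$us_timestamps) != n_us)
    stop_msopus("us_timestamps length (%d) does not match image count (%d)",
                length(scan$us_timestamps), n_us,
                class = "msopus_validation_error")
  if (length(scan$oa_timestamps) != n_oa)
    stop_msopus("oa_timestamps length (%d) does not match image count (%d)",
                length(scan$oa_timestamps), n_oa,
                class = "msopus_validation_error")
  if (length(scan$oa_wavelengths) != n_oa)
    stop_msopus("oa_wavelengths length (%d) does not match image count (%d)",
                length(scan$oa_wavelengths), n_oa,
                class = "msopus_validation_error")
  if (n_us > 1 && any(diff(scan$us_timestamps) <= 0))
    stop_msopus("us_timestamps must be strictly increasing",
                class = "msopus_validation_error")
  if (n_oa > 1 && any(diff(scan$oa_timestamps) <= 0))
    stop_msopus("oa_timestamps must be strictly increasing",
                class = "msopus_validation_error")
  n_lambda <- length(scan$wavelengths)
  wl <- scan$oa_wavelengths
  if (n_oa > n_lambda &&
      any(wl[seq_len(n_oa - n_lambda)] != wl[seq_len(n_oa - n_lambda) + n_lambda]))
    stop_msopus("oa_wavelengths must cycle with period %d", n_lambda,
                class = "msopus_validation_error")
  # every full cycle must cover the preset exactly once
  if (n_oa >= n_lambda &&
      length(unique(wl[seq_len(n_lambda)])) != n_lambda)
    stop_msopus("a wavelength repeats within one cycle",
                class = "msopus_validation_error")
  invisible(scan)
}

#' @export
print.msopus_scan <- function(x, ...) {
  cat(sprintf("MS-OPUS scan%s\n",
              if (!is.null(x$meta$scan_id)) paste0(" '", x$meta$scan_id, "'") else ""))
  cat(sprintf("  US : %d images %dx%d, t = [%.3f, %.3f] s\n",
              dim(x$us_images)[3], dim(x$us_images)[1], dim(x$us_images)[2],
              min(x$us_timestamps), max(x$us_timestamps)))
  cat(sprintf("  OA : %d images %dx%d, %d wavelengths (%g-%g nm)\n",
              dim(x$oa_images)[3], dim(x$oa_images)[1], dim(x$oa_images)[2],
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  MS frames: %d\n", n_ms_frames(x)))
  invisible(x)
}

#' Number of sliding multispectral frames in a scan
#'
#' An MS frame is any window of `N_lambda` consecutive OA images, so a scan
#' holds `N_OA - N_lambda + 1` overlapping frames.
#' @param scan an `msopus_scan`.
#' @return integer count (0 when the scan is shorter than one wavelength cycle).
#' @export
n_ms_frames <- function(scan) {
  max(0L, dim(scan$oa_images)[3] - length(scan$wavelengths) + 1L)
}

#' US image indices acquired during one MS frame
#'
#' Returns the ordered indices `s` of all US images whose timestamps fall in
#' the closed interval spanned by the frame's first and last OA image,
#' `t_OA(k) <= t_US(i) <= t_OA(k + N_lambda - 1)`.
#'
#' @param scan an `msopus_scan`.
#' @param k MS frame start index, `1 <= k <= n_ms_frames(scan)`.
#' @return ascending integer vector, possibly empty.
#' @export
us_indices_for_frame <- function(scan, k) {
  n_ms <- n_ms_frames(scan)
  if (length(k) != 1L || k < 1L || k > n_ms)
    stop_msopus("frame index k=%s out of range 1..%d", toString(k), n_ms,
                class = "msopus_index_error")
  n_lambda <- length(scan$wavelengths)
  lo <- scan$oa_timestamps[k]
  hi <- scan$oa_timestamps[k + n_lambda - 1L]
  which(scan$us_timestamps >= lo & scan$us_timestamps <= hi)
}

#' Enumerate all sliding MS frames of a scan
#'
#' Consecutive frames overlap in `N_lambda - 1` OA images; a frame may start
#' at any OA image, not only at the first wavelength of the preset.
#'
#' @param scan an `msopus_scan`.
#' @return list of length `n_ms_frames(scan)`; element `k` is a list with
#'   `k` (start index), `oa_indices` (the `N_lambda` consecutive OA indices),
#'   `wavelength_order` (permutation of `oa_indices` positions sorting the
#'   frame by ascending wavelength) and `s` (see [us_indices_for_frame()]).
#' @export
ms_frames <- function(scan) {
  n_lambda <- length(scan$wavelengths)
  n_oa <- dim(scan$oa_images)[3]
  if (n_oa < n_lambda)
    stop_msopus("scan has %d OA images, fewer than the %d-wavelength preset",
                n_oa, n_lambda, class = "msopus_insufficient_data_error")
  n_ms <- n_oa - n_lambda + 1L
  t_us <- scan$us_timestamps
  t_oa <- scan$oa_timestamps
  lapply(seq_len(n_ms), function(k) {
    idx <- k:(k + n_lambda - 1L)
    list(k = k,
         oa_indices = idx,
         wavelength_order = order(scan$oa_wavelengths[idx]),
         s = which(t_us >= t_oa[k] & t_us <= t_oa[k + n_lambda - 1L]))
  })
}

#' Maximum number of US images per MS frame
#'
#' `K = max_k |s^(k)|` bounds the number of dissimilarity-matrix rows (lags)
#' that ever need to be computed for a scan.
#' @param scan an `msopus_scan`.
#' @return integer `K` (0 if every frame has an empty `s`).
#' @export
max_us_per_frame <- function(scan) {
  frames <- ms_frames(scan)
  max(0L, vapply(frames, function(f) length(f$s), integer(1)))
}

#' Write a scan to an HDF5 container
#'
#' Layout: datasets `/us/images` (float32, file dims `N_US x H x W`),
#' `/us/timestamps`, `/oa/images`, `/oa/timestamps`, `/oa/wavelengths`
#' (float64), and root attributes `scan_id`, `f_us_hz`, `f_oa_hz`.
#' Images are stored in single precision, as produced by the acquisition
#' hardware; pass data already on the float32 grid (the simulator does) for
#' bit-exact round trips.
#'
#' @param scan an `msopus_scan`.
#' @param path output file path (overwritten).
#' @return `path`, invisibly.
#' @export
save_scan <- function(scan, path) {
  validate_scan(scan)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "us")
  rhdf5::h5createGroup(path, "oa")
  write_f32 <- function(arr, name) {
    # file dims (N, H, W): rhdf5 reverses R dims, so permute to (W, H, N)
    a <- aperm(arr, c(2, 1, 3))
    rhdf5::h5createDataset(path, name, dims = dim(a),
                           H5type = "H5T_IEEE_F32LE", chunk = dim(a),
                           level = 0)
    rhdf5::h5write(a, path, name)
  }
  write_f32(scan$us_images, "us/images")
  rhdf5::h5write(scan$us_timestamps, path, "us/timestamps")
  write_f32(scan$oa_images, "oa/images")
  rhdf5::h5write(scan$oa_timestamps, path, "oa/timestamps")
  rhdf5::h5write(scan$oa_wavelengths, path, "oa/wavelengths")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(as.character(scan$meta$scan_id %||% ""), fid, "scan_id")
  rhdf5::h5writeAttribute(as.double(scan$meta$f_us_hz %||% NA_real_), fid, "f_us_hz")
  rhdf5::h5writeAttribute(as.double(scan$meta$f_oa_hz %||% NA_real_), fid, "f_oa_hz")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a scan from an HDF5 container
#'
#' Expects the layout written by [save_scan()]; unknown datasets are ignored.
#' All scan invariants are re-validated after reading.
#'
#' @param path HDF5 file path.
#' @return an `msopus_scan`.
#' @export
load_scan <- function(path) {
  if (!file.exists(path))
    stop_msopus("scan file not found: %s", path, class = "msopus_format_error")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  present <- file.path(contents$group, contents$name)
  present <- sub("^//", "/", present)
  required <- c("/us/images", "/us/timestamps", "/oa/images",
                "/oa/timestamps", "/oa/wavelengths")
  missing <- setdiff(required, present)
  if (length(missing))
    stop_msopus("scan file %s is missing dataset(s): %s", path,
                paste(missing, collapse = ", "), class = "msopus_format_error")
  read_img <- function(name) aperm(rhdf5::h5read(path, name), c(2, 1, 3))
  attrs <- rhdf5::h5readAttributes(path, "/")
  meta <- list(scan_id = as.character(attrs$scan_id %||% ""),
               f_us_hz = as.double(attrs$f_us_hz %||% NA_real_),
               f_oa_hz = as.double(attrs$f_oa_hz %||% NA_real_))
  msopus_scan(us_images = read_img("us/images"),
              us_timestamps = as.double(rhdf5::h5read(path, "us/timestamps")),
              oa_images = read_img("oa/images"),
              oa_timestamps = as.double(rhdf5::h5read(path, "oa/timestamps")),
              oa_wavelengths = as.double(rhdf5::h5read(path, "oa/wavelengths")),
              meta = meta)
}
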