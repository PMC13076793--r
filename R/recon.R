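# Envelope reconstruction: RF frames -> filtered 3D envelope volume and the
# standard projections (MAP, depth-encoded, B-scan).

new_recon_volume <- function(amplitude, voxel_pitch_um,
                             origin_um = c(0, 0, 0), provenance = list()) {
  stopifnot(length(dim(amplitude)) == 3)
  structure(list(amplitude = amplitude,
                 voxel_pitch_um = as.numeric(voxel_pitch_um),
                 origin_um = as.numeric(origin_um),
                 provenance = provenance),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf("<recon_volume: %d x %d x %d voxels at %g x %g x %g um>\n",
              d[1], d[2], d[3], x$voxel_pitch_um[1], x$voxel_pitch_um[2],
              x$voxel_pitch_um[3]))
  invisible(x)
}

as_volume_array <- function(volume) {
  if (inherits(volume, "recon_volume")) volume$amplitude else volume
}

volume_pitch <- function(volume, default = c(2, 2, 3)) {
  if (inherits(volume, "recon_volume")) volume$voxel_pitch_um
  else if (inherits(volume, "vessel_mask")) volume$voxel_pitch_um
  else default
}

#' Upper envelope of an RF trace
#'
#' Magnitude of the analytic signal (FFT-based Hilbert quadrature); length
#' preserved, parameter-free.
#'
#' @param rf_trace Numeric RF samples (finite).
#' @return Nonnegative envelope of the same length.
#' @export
extract_envelope <- function(rf_trace) {
  stop_if(!length(rf_trace), "empty RF trace")
  stop_if(any(!is.finite(rf_trace)), "RF trace contains non-finite values")
  drop(envelope_matrix(matrix(rf_trace, ncol = 1)))
}

# analytic-signal envelope per column
envelope_matrix <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(abs(m))
  X <- stats::mvfft(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::mvfft(X * h, inverse = TRUE)) / n
}

#' Convert a time-sample index to depth
#'
#' One-way time of flight: `depth = v * index / f_s` (the acoustic wave
#' travels absorber to transducer only). At the defaults the per-sample
#' pitch is 1540 / 500 = 3.08 um, i.e. the nominal 3-um axial pixel.
#'
#' @param sample_index 0-based sample index (numeric, may be fractional).
#' @param acquisition An [acquisition_spec()].
#' @return Depth in um.
#' @export
time_to_depth <- function(sample_index, acquisition) {
  stop_if(any(sample_index < 0), "sample_index must be >= 0")
  acquisition$sound_speed_mps * sample_index / acquisition$sampling_rate_msps
}

#' Assemble an envelope volume from RF frames
#'
#' Extracts the analytic-signal envelope of every A-line and resamples it by
#' linear interpolation from the native `v / f_s` (3.08 um) sample pitch onto
#' a uniform axial lattice (default exactly 3 um so voxel bookkeeping
#' matches the nominal 2 x 2 x 3 um voxel; pass `z_pitch_um = NULL` to keep
#' the native pitch).
#'
#' @param frames An `rf_frameset`.
#' @param z_pitch_um Output axial pitch in um (default 3).
#' @param depth_extent_um Depth of the deepest output voxel; defaults to the
#'   extent recorded in `frames`, else the full time axis.
#' @return A `recon_volume`.
#' @export
assemble_volume <- function(frames, z_pitch_um = 3, depth_extent_um = NULL) {
  stopifnot(inherits(frames, "rf_frameset"))
  d <- dim(frames$samples)
  n_t <- d[3]
  acq <- frames$acquisition
  native_z <- time_to_depth(seq_len(n_t) - 1, acq)
  if (is.null(z_pitch_um)) z_pitch_um <- acq$sound_speed_mps / acq$sampling_rate_msps
  depth_extent_um <- depth_extent_um %||% frames$depth_extent_um %||%
    max(native_z)
  depth_extent_um <- min(depth_extent_um, max(native_z))
  nz <- as.integer(floor(depth_extent_um / z_pitch_um + 1e-9)) + 1L
  z_out <- (seq_len(nz) - 1) * z_pitch_um
  rf <- matrix(frames$samples, nrow = d[1] * d[2], ncol = n_t)
  env <- t(envelope_matrix(t(rf)))
  native_pitch <- acq$sound_speed_mps / acq$sampling_rate_msps
  out <- matrix(0, d[1] * d[2], nz)
  for (j in seq_len(nz)) {
    # linear interpolation on the uniform native grid, vectorized over A-lines
    si <- z_out[j] / native_pitch
    i0 <- min(floor(si), n_t - 1)
    fr <- si - i0
    out[, j] <- env[, i0 + 1] * (1 - fr) + env[, min(i0 + 2, n_t)] * fr
  }
  amp <- array(out, dim = c(d[1], d[2], nz))
  new_recon_volume(amp, c(frames$scan_pitch_um, z_pitch_um),
                   provenance = list(sampling_rate_msps = acq$sampling_rate_msps,
                                     sound_speed_mps = acq$sound_speed_mps,
                                     native_pitch_um = acq$sound_speed_mps /
                                       acq$sampling_rate_msps))
}

#' 3D median filter
#'
#' Per-voxel median over an odd cubic window with replicate padding at the
#' borders; the standard 3 x 3 x 3 voxel despeckling step of the
#' reconstruction pipeline.
#'
#' @param volume A `recon_volume` or 3D array.
#' @param window Odd window size (default 3).
#' @return Same type as the input.
#' @export
median_filter_3d <- function(volume, window = 3L) {
  stop_if(window < 1 || window %% 2 == 0, "window must be odd and >= 1")
  a <- as_volume_array(volume)
  f <- array(cpp_median_filter3(as.numeric(a), as.integer(dim(a)),
                                as.integer(window)), dim = dim(a))
  if (inherits(volume, "recon_volume")) {
    volume$amplitude <- f
    volume
  } else f
}

#' Maximum amplitude projection
#'
#' @param volume A `recon_volume` or 3D array.
#' @return Matrix (x, y): per-pixel maximum over depth.
#' @export
map_projection <- function(volume) {
  a <- as_volume_array(volume)
  stop_if(!length(a), "empty volume")
  out <- a[, , 1]
  nz <- dim(a)[3]
  if (nz > 1) for (k in 2:nz) out <- pmax(out, a[, , k])
  out
}

#' Depth-encoded projection
#'
#' Per lateral position, the depth (um) of the amplitude argmax over z.
#' Pixels whose MAP falls below `amplitude_floor` are masked (`NA`); the
#' default floor is the Otsu threshold of the MAP.
#'
#' @param volume A `recon_volume` or 3D array.
#' @param amplitude_floor Background floor (>= 0), or `NULL` for Otsu.
#' @return Matrix of depths in um with `NA` background.
#' @export
depth_encoded_projection <- function(volume, amplitude_floor = NULL) {
  a <- as_volume_array(volume)
  pz <- volume_pitch(volume)[3]
  best <- a[, , 1]
  arg <- array(1, dim(a)[1:2])
  nz <- dim(a)[3]
  if (nz > 1) for (k in 2:nz) {
    s <- a[, , k]
    upd <- s > best
    best[upd] <- s[upd]
    arg[upd] <- k
  }
  if (is.null(amplitude_floor)) amplitude_floor <- otsu_threshold(best)
  stop_if(amplitude_floor < 0, "amplitude_floor must be >= 0")
  depth <- (arg - 1) * pz
  depth[best < amplitude_floor] <- NA_real_
  depth
}

#' Extract a B-scan slice
#'
#' @param volume A `recon_volume` or 3D array.
#' @param scan_line 1-based index of the line.
#' @param axis `"y"` (default): slice at `y = scan_line`, returning an
#'   (x, depth) image; `"x"`: slice at `x = scan_line`, returning (y, depth).
#' @return Matrix (lateral, depth).
#' @export
extract_bscan <- function(volume, scan_line, axis = c("y", "x")) {
  axis <- match.arg(axis)
  a <- as_volume_array(volume)
  lim <- if (axis == "y") dim(a)[2] else dim(a)[1]
  stop_if(scan_line < 1 || scan_line > lim, "scan_line out of range")
  if (axis == "y") a[, scan_line, ] else a[scan_line, , ]
}
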