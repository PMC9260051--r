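#' Golden-angle Archimedean spiral trajectory
#'
#' Constant-density Archimedean interleaf with `matrix / (2 * n_interleaves)`
#' turns, sampled uniformly in angle. The union of the `n_interleaves` base
#' rotations (spaced 2 pi / n_interleaves) meets Nyquist for the configured
#' matrix; successive TRs use a single interleaf rotated by the golden angle
#' (111.246 degrees). Coordinates are in cycles/FOV, so |k| <= matrix / 2
#' with the field of view normalized to 1.
#'
#' @param matrix Reconstruction matrix size (isotropic).
#' @param n_interleaves Number of interleaves forming a fully sampled set
#'   (default 48; one interleaf is acquired per TR, i.e. 48-fold
#'   undersampling).
#' @param readout_ms Readout duration (ms).
#' @param dwell_us Sampling dwell time (us); the number of samples per
#'   readout is `round(readout_ms * 1000 / dwell_us)`.
#' @param rotation_per_tr_deg Rotation increment between TRs (deg).
#' @return An object of class `cmrf_spiral` with the base interleaf
#'   coordinates (`n_samples` x 2), counts and rotation increment.
#' @export
make_spiral <- function(matrix = 192L, n_interleaves = 48L, readout_ms = 3.4,
                        dwell_us = 2.5, rotation_per_tr_deg = 111.246) {
  if (n_interleaves < 1) stop("n_interleaves must be >= 1")
  n_samples <- as.integer(round(readout_ms * 1000 / dwell_us))
  if (n_samples < 2) stop("readout/dwell yield too few samples")
  turns <- matrix / (2 * n_interleaves)
  if (turns <= 0) stop("infeasible interleaf turn count")
  k_max <- matrix / 2
  s <- seq(0, n_samples - 1) / n_samples
  theta <- 2 * pi * turns * s
  r <- k_max * s
  structure(list(
    base = cbind(kx = r * cos(theta), ky = r * sin(theta)),
    n_samples = n_samples, n_interleaves = as.integer(n_interleaves),
    matrix = as.integer(matrix), turns = turns, k_max = k_max,
    rotation_per_tr_deg = rotation_per_tr_deg
  ), class = "cmrf_spiral")
}

#' @export
print.cmrf_spiral <- function(x, ...) {
  cat(sprintf(
    "Spiral trajectory: %d interleaves, %.2f turns, %d samples/readout, k_max %.1f, %.3f deg/TR\n",
    x$n_interleaves, x$turns, x$n_samples, x$k_max, x$rotation_per_tr_deg))
  invisible(x)
}

rotate_coords <- function(coords, angle_deg) {
  a <- angle_deg * pi / 180
  R <- base::matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  out <- coords %*% R
  colnames(out) <- c("kx", "ky")
  out
}

#' Spiral sample coordinates for one time frame
#'
#' Frame i uses the base interleaf rotated by `(i - 1)` golden-angle
#' increments. With `full_sampling = TRUE` the frame instead contains the
#' complete Nyquist set of all base interleaves (rotated jointly).
#'
#' @param traj A [make_spiral()] trajectory.
#' @param i Frame (TR) index, 1-based.
#' @param full_sampling Use all interleaves for this frame.
#' @return Matrix of k-space coordinates (cycles/FOV), columns kx, ky.
#' @export
spiral_frame_coords <- function(traj, i, full_sampling = FALSE) {
  base_set <- if (full_sampling) {
    do.call(rbind, lapply(seq_len(traj$n_interleaves) - 1L, function(j)
      rotate_coords(traj$base, j * 360 / traj$n_interleaves)))
  } else {
    traj$base
  }
  rotate_coords(base_set, (i - 1) * traj$rotation_per_tr_deg)
}

nudft_phasors <- function(n, k) {
  pos <- seq(0, n - 1) - n %/% 2
  exp(-2i * pi * outer(pos / n, k))
}

#' Exact non-uniform discrete Fourier transform (forward / adjoint)
#'
#' Evaluates the type-2 NUDFT of a Cartesian image at arbitrary k-space
#' locations (and its exact adjoint), using a separable phasor
#' factorization so the work is two complex matrix products per call. The
#' convention matches the centered orthonormal FFT used throughout the
#' package: image positions span `[-n/2, n/2)` voxels, coordinates are in
#' cycles/FOV, and on integer coordinates the forward transform equals the
#' centered orthonormal FFT. The pair satisfies the adjoint (inner-product)
#' test to machine precision.
#'
#' @param image Complex matrix (n_y x n_x).
#' @param coords m x 2 matrix of (kx, ky) in cycles/FOV; |kx| <= n_x / 2,
#'   |ky| <= n_y / 2.
#' @return `nudft_forward`: complex vector of m samples.
#' @export
nudft_forward <- function(image, coords) {
  n_y <- nrow(image); n_x <- ncol(image)
  check_coords(coords, n_y, n_x)
  Ey <- nudft_phasors(n_y, coords[, 2])
  Ex <- nudft_phasors(n_x, coords[, 1])
  colSums(Ey * (image %*% Ex)) / sqrt(n_y * n_x)
}

#' @rdname nudft_forward
#' @param samples Complex vector of m k-space samples.
#' @param n_y,n_x Output image size.
#' @return `nudft_adjoint`: complex n_y x n_x image.
#' @export
nudft_adjoint <- function(samples, coords, n_y, n_x) {
  check_coords(coords, n_y, n_x)
  Ey <- nudft_phasors(n_y, coords[, 2])
  Ex <- nudft_phasors(n_x, coords[, 1])
  Conj(Ey) %*% (as.vector(samples) * t(Conj(Ex))) / sqrt(n_y * n_x)
}

check_coords <- function(coords, n_y, n_x) {
  if (!is.matrix(coords) || ncol(coords) != 2)
    stop("coords must be an m x 2 matrix")
  if (any(abs(coords[, 1]) > n_x / 2 + 1e-9) ||
      any(abs(coords[, 2]) > n_y / 2 + 1e-9))
    stop("k-space coordinates exceed the supported band |k| <= matrix/2")
  invisible(TRUE)
}

#' Density compensation weights for non-Cartesian samples
#'
#' `"ramp"` weights are proportional to |k| (the analytic compensation for
#' a constant-density Archimedean spiral sampled uniformly in angle), with
#' the DC sample given the innermost radial step. `"counts"` weights are
#' one over the number of samples landing in the same Cartesian cell.
#' Weights are normalized to unit mean.
#'
#' @param coords m x 2 k-space coordinates (cycles/FOV).
#' @param matrix Grid size (needed for `"counts"`).
#' @param method `"ramp"` or `"counts"`.
#' @return Numeric weight vector of length m.
#' @export
density_weights <- function(coords, matrix = NULL, method = c("ramp", "counts")) {
  method <- match.arg(method)
  if (method == "ramp") {
    r <- sqrt(coords[, 1]^2 + coords[, 2]^2)
    dk <- stats::median(diff(sort(unique(round(r, 6)))))
    w <- pmax(r, dk / 2)
  } else {
    stopifnot(!is.null(matrix))
    cell <- nearest_cell(coords, matrix)
    id <- paste(cell[, 1], cell[, 2])
    w <- 1 / as.vector(table(id)[id])
  }
  w / mean(w)
}

# round-half-toward-negative nearest integer cell, clamped to the grid
nearest_cell <- function(coords, matrix) {
  half <- matrix %/% 2
  cl <- ceiling(coords - 0.5)
  cl[cl > half - 1] <- half - 1
  cl[cl < -half] <- -half
  storage.mode(cl) <- "integer"
  cl
}

#' Simulate a spiral cardiac MRF acquisition
#'
#' Per-voxel fingerprints are simulated for the distinct tissue (T1, T2)
#' pairs of the phantom, scaled by the complex M0 map to form the MRF image
#' series; frame i is sampled on interleaf i of the golden-angle spiral
#' through coil-weighted exact NUDFTs; complex Gaussian noise is added with
#' a standard deviation (per real/imaginary component) equal to
#' `noise_pct`/100 of the maximum DC-sample magnitude over frames and
#' coils.
#'
#' @param phantom A [make_cardiac_phantom()] object.
#' @param schedule A [build_schedule()] object.
#' @param csm A [make_coil_maps()] object of matching matrix size.
#' @param traj A [make_spiral()] trajectory.
#' @param noise_pct Noise standard deviation as percent of the DC maximum.
#' @param seed Integer seed for the noise stream.
#' @param noise_sigma Optional absolute noise SD overriding the DC-relative
#'   calibration.
#' @param full_sampling Sample the complete interleaf set every frame
#'   (Nyquist-complete reference acquisitions).
#' @param n_states EPG state count for the signal simulation.
#' @return An object of class `cmrf_spiral_data`: `y` (complex array
#'   t x n_coils x n_samples), `traj`, `schedule`, `rhythm`, `noise_pct`,
#'   `noise_sigma`, `full_sampling`, `seed`.
#' @export
simulate_acquisition <- function(phantom, schedule, csm, traj,
                                 noise_pct = 0.1, seed = 1L,
                                 noise_sigma = NULL, full_sampling = FALSE,
                                 n_states = 20L) {
  if (noise_pct < 0) stop("noise_pct must be non-negative")
  stopifnot(dim(csm$S)[1] == phantom$n_y, dim(csm$S)[2] == phantom$n_x)
  t_total <- schedule$total_trs
  n_coils <- csm$n_coils
  fg <- phantom_fingerprints(phantom, schedule, n_states)
  n_samp <- traj$n_samples * (if (full_sampling) traj$n_interleaves else 1L)
  y <- array(0 + 0i, dim = c(t_total, n_coils, n_samp))
  coil_imgs <- lapply(seq_len(n_coils), function(cc) csm$S[, , cc])
  for (i in seq_len(t_total)) {
    co <- spiral_frame_coords(traj, i, full_sampling)
    frame <- base::matrix(fg$voxel_signal[, i], phantom$n_y, phantom$n_x)
    for (cc in seq_len(n_coils)) {
      y[i, cc, ] <- nudft_forward(frame * coil_imgs[[cc]], co)
    }
  }
  # sample index 1 of each interleaf sits exactly at k = 0 (the DC sample)
  dc_max <- max(Mod(y[, , 1]))
  sigma <- if (!is.null(noise_sigma)) noise_sigma else noise_pct / 100 * dc_max
  if (sigma > 0) {
    y <- y + with_seed(derive_seed(seed, "kspace-noise"), {
      n <- length(y)
      complex(real = rnorm(n, 0, sigma), imaginary = rnorm(n, 0, sigma))
    })
  }
  structure(list(y = y, traj = traj, schedule = schedule,
                 rhythm = schedule$rhythm, noise_pct = noise_pct,
                 noise_sigma = sigma, full_sampling = full_sampling,
                 seed = as.integer(seed)),
            class = "cmrf_spiral_data")
}

#' @export
print.cmrf_spiral_data <- function(x, ...) {
  d <- dim(x$y)
  cat(sprintf(
    "Spiral MRF data: %d frames x %d coils x %d samples (noise sigma %.3g)\n",
    d[1], d[2], d[3], x$noise_sigma))
  invisible(x)
}

# signal per voxel over time from distinct tissue pairs (piecewise-constant
# phantoms need only one EPG run per tissue)
phantom_fingerprints <- function(phantom, schedule, n_states = 20L) {
  fg_mask <- phantom$labels > 0
  pairs <- unique(data.frame(t1 = phantom$t1_map[fg_mask],
                             t2 = phantom$t2_map[fg_mask]))
  F <- simulate_fingerprint(pairs$t1, pairs$t2, schedule, n_states)
  if (is.null(dim(F))) F <- base::matrix(F, nrow = 1)
  n_vox <- length(phantom$t1_map)
  voxel_signal <- base::matrix(0 + 0i, n_vox, schedule$total_trs)
  key_vox <- paste(phantom$t1_map, phantom$t2_map)
  key_pairs <- paste(pairs$t1, pairs$t2)
  idx <- match(key_vox, key_pairs)
  inside <- which(fg_mask)
  voxel_signal[inside, ] <- F[idx[inside], , drop = FALSE] *
    as.vector(phantom$m0_map)[inside]
  list(voxel_signal = voxel_signal, pairs = pairs)
}
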