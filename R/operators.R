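# Forward encoding operators shared by the subspace reconstructions.
# The MRF image series is modeled as x = x_k V_k^H; frame i is the basis
# contraction with column i of V_k^H, coil weighting, and Fourier sampling
# (Cartesian masked FFT after GROG, or exact NUDFT on the spiral).

basis_frame_image <- function(x_k, V_k, i) {
  n_y <- dim(x_k)[1]; n_x <- dim(x_k)[2]; k <- dim(x_k)[3]
  out <- matrix(0 + 0i, n_y, n_x)
  for (j in seq_len(k)) out <- out + x_k[, , j] * Conj(V_k[i, j])
  out
}

#' Cartesian MRF forward model for one time frame
#'
#' Implements the per-frame encoding used by the self-supervised
#' reconstruction: multiply the spatial basis images by the coil
#' sensitivities, apply the centered orthonormal FFT per coil, contract the
#' basis dimension with column i of the conjugated temporal basis
#' (projecting the subspace to time frame i), then apply the frame's
#' sampling mask and the density compensation function.
#'
#' @param x_k Complex basis-image array (n_y x n_x x k).
#' @param csm Coil maps (`cmrf_coil_maps`).
#' @param subspace A [compute_subspace()] object.
#' @param P_i Logical sampling mask (n_y x n_x) of frame i.
#' @param W Density compensation map (n_y x n_x).
#' @param i Frame index (1-based), within the subspace time dimension.
#' @return Complex array (n_y x n_x x n_coils) of estimated k-space for
#'   frame i, supported on `P_i`.
#' @export
forward_model_frame <- function(x_k, csm, subspace, P_i, W, i) {
  if (i < 1 || i > nrow(subspace$V_k)) stop("frame index out of range")
  n_y <- dim(x_k)[1]; n_x <- dim(x_k)[2]
  n_coils <- dim(csm$S)[3]
  frame <- basis_frame_image(x_k, subspace$V_k, i)
  out <- array(0 + 0i, dim = c(n_y, n_x, n_coils))
  WP <- W * P_i
  for (cc in seq_len(n_coils)) {
    out[, , cc] <- WP * ft2c(frame * csm$S[, , cc])
  }
  out
}

# full spiral forward operator: basis images -> all frames' samples
spiral_forward_op <- function(x_k, csm, V_k, traj, full_sampling = FALSE) {
  t_total <- nrow(V_k)
  n_coils <- dim(csm$S)[3]
  n_samp <- traj$n_samples * (if (full_sampling) traj$n_interleaves else 1L)
  y <- array(0 + 0i, dim = c(t_total, n_coils, n_samp))
  for (i in seq_len(t_total)) {
    co <- spiral_frame_coords(traj, i, full_sampling)
    frame <- basis_frame_image(x_k, V_k, i)
    for (cc in seq_len(n_coils)) {
      y[i, cc, ] <- nudft_forward(frame * csm$S[, , cc], co)
    }
  }
  y
}

spiral_adjoint_op <- function(y, csm, V_k, traj, full_sampling = FALSE) {
  t_total <- nrow(V_k)
  n_y <- dim(csm$S)[1]; n_x <- dim(csm$S)[2]; n_coils <- dim(csm$S)[3]
  k <- ncol(V_k)
  x_k <- array(0 + 0i, dim = c(n_y, n_x, k))
  for (i in seq_len(t_total)) {
    co <- spiral_frame_coords(traj, i, full_sampling)
    img <- matrix(0 + 0i, n_y, n_x)
    for (cc in seq_len(n_coils)) {
      img <- img + Conj(csm$S[, , cc]) * nudft_adjoint(y[i, cc, ], co, n_y, n_x)
    }
    for (j in seq_len(k)) x_k[, , j] <- x_k[, , j] + img * V_k[i, j]
  }
  x_k
}

# Cartesian (GROG) forward/adjoint over all frames; data carry W already
cart_forward_op <- function(x_k, csm, V_k, P, W) {
  t_total <- nrow(V_k)
  n_y <- dim(x_k)[1]; n_x <- dim(x_k)[2]; n_coils <- dim(csm$S)[3]
  y <- array(0 + 0i, dim = c(t_total, n_coils, n_y, n_x))
  coil_ft <- array(0 + 0i, dim = c(n_y, n_x, n_coils, dim(x_k)[3]))
  for (j in seq_len(dim(x_k)[3])) {
    for (cc in seq_len(n_coils)) {
      coil_ft[, , cc, j] <- ft2c(x_k[, , j] * csm$S[, , cc])
    }
  }
  for (i in seq_len(t_total)) {
    WP <- W * P[i, , ]
    for (cc in seq_len(n_coils)) {
      acc <- matrix(0 + 0i, n_y, n_x)
      for (j in seq_len(dim(x_k)[3])) {
        acc <- acc + coil_ft[, , cc, j] * Conj(V_k[i, j])
      }
      y[i, cc, , ] <- WP * acc
    }
  }
  y
}

cart_adjoint_op <- function(y, csm, V_k, P, W) {
  t_total <- nrow(V_k)
  n_y <- dim(y)[3]; n_x <- dim(y)[4]; n_coils <- dim(csm$S)[3]
  k <- ncol(V_k)
  # accumulate the k-space basis coefficients first, then one IFFT per
  # (coil, basis) pair instead of per frame
  acc <- array(0 + 0i, dim = c(n_y, n_x, n_coils, k))
  for (i in seq_len(t_total)) {
    WP <- W * P[i, , ]
    for (cc in seq_len(n_coils)) {
      m <- WP * y[i, cc, , ]
      for (j in seq_len(k)) acc[, , cc, j] <- acc[, , cc, j] + m * V_k[i, j]
    }
  }
  x_k <- array(0 + 0i, dim = c(n_y, n_x, k))
  for (j in seq_len(k)) {
    img <- matrix(0 + 0i, n_y, n_x)
    for (cc in seq_len(n_coils)) {
      img <- img + Conj(csm$S[, , cc]) * ift2c(acc[, , cc, j])
    }
    x_k[, , j] <- img
  }
  x_k
}
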