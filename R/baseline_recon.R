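#' Per-TR gridding followed by dictionary matching
#'
#' The classical MRF baseline: one (heavily undersampled) image is gridded
#' per TR from the spiral samples using the exact NUDFT adjoint with ramp
#' density weights and coil combination with the supplied sensitivity
#' maps; every voxel's time signal is then matched to the dictionary row
#' maximizing the magnitude of the normalized inner product. M0 is the
#' complex least-squares scale between the winning fingerprint and the
#' measured signal.
#'
#' @param data A [simulate_acquisition()] object.
#' @param dictionary A [build_dictionary()] for the same schedule.
#' @param csm Coil maps used for coil combination.
#' @return A `cmrf_parameter_maps` object: `t1_map`, `t2_map` (ms),
#'   `m0_map` (complex), `background` (logical map of voxels with zero
#'   signal).
#' @export
direct_match <- function(data, dictionary, csm) {
  if (dictionary$schedule$total_trs != dim(data$y)[1])
    stop("dictionary schedule does not match the data schedule")
  X <- gridded_time_series(data, csm)
  match_time_series(X, dictionary$D, dictionary$entries,
                    c(dim(csm$S)[1], dim(csm$S)[2]))
}

# voxel x time matrix of coil-combined per-TR gridded images; for
# Nyquist-complete (fully sampled) frames the density-compensated adjoint
# is refined by a few preconditioned Richardson iterations so the frame
# images are essentially exact inverses rather than approximate ones
gridded_time_series <- function(data, csm, refine_iters = 4L) {
  n_y <- dim(csm$S)[1]; n_x <- dim(csm$S)[2]; n_coils <- dim(csm$S)[3]
  t_total <- dim(data$y)[1]
  rss2 <- pmax(apply(Mod(csm$S)^2, c(1, 2), sum), 1e-12)
  X <- matrix(0 + 0i, n_y * n_x, t_total)
  combine <- function(samples, co, w) {
    img <- matrix(0 + 0i, n_y, n_x)
    for (cc in seq_len(n_coils)) {
      img <- img + Conj(csm$S[, , cc]) *
        nudft_adjoint(w * samples[cc, ], co, n_y, n_x)
    }
    img / rss2
  }
  for (i in seq_len(t_total)) {
    co <- spiral_frame_coords(data$traj, i, data$full_sampling)
    # ramp is the analytic density for a single uniform-angle Archimedean
    # interleaf; fully sampled frames use cell counts (uniform for
    # Cartesian-complete references) and are refined to the exact
    # least-squares frame below
    w <- density_weights(co, data$traj$matrix,
                         if (data$full_sampling) "counts" else "ramp")
    y_i <- matrix(data$y[i, , ], nrow = n_coils)
    fwd <- function(img) {
      out <- matrix(0 + 0i, n_coils, ncol(y_i))
      for (cc in seq_len(n_coils)) {
        out[cc, ] <- nudft_forward(img * csm$S[, , cc], co)
      }
      out
    }
    img <- matrix(0 + 0i, n_y, n_x)
    if (data$full_sampling) {
      # preconditioned steepest descent with exact line search
      for (it in seq_len(refine_iters + 1L)) {
        r <- y_i - fwd(img)
        d <- combine(r, co, w)
        Ad <- fwd(d)
        den <- sum(Mod(Ad)^2)
        if (den <= 1e-30 * sum(Mod(y_i)^2)) break
        img <- img + (sum(Conj(Ad) * r) / den) * d
      }
    } else {
      img <- combine(y_i, co, w)
    }
    X[, i] <- as.vector(img)
  }
  X
}

match_time_series <- function(X, D, entries, dims, chunk = 1024L) {
  p <- nrow(D)
  row_norm2 <- rowSums(Mod(D)^2)
  Dn <- D / sqrt(row_norm2)
  n_vox <- nrow(X)
  best <- integer(n_vox)
  m0 <- complex(n_vox)
  sig_norm <- sqrt(rowSums(Mod(X)^2))
  bg <- sig_norm <= 1e-12 * max(sig_norm, 0)
  for (lo in seq(1, n_vox, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_vox)
    C <- Conj(Dn) %*% t(X[lo:hi, , drop = FALSE])        # p x chunk
    idx <- max.col(t(Mod(C)), ties.method = "first")
    best[lo:hi] <- idx
    m0[lo:hi] <- C[cbind(idx, seq_along(idx))] / sqrt(row_norm2[idx])
  }
  best[bg] <- NA_integer_
  t1 <- t2 <- rep(0, n_vox)
  t1[!bg] <- entries$t1_ms[best[!bg]]
  t2[!bg] <- entries$t2_ms[best[!bg]]
  m0[bg] <- 0 + 0i
  structure(list(
    t1_map = matrix(t1, dims[1], dims[2]),
    t2_map = matrix(t2, dims[1], dims[2]),
    m0_map = matrix(m0, dims[1], dims[2]),
    background = matrix(bg, dims[1], dims[2])
  ), class = "cmrf_parameter_maps")
}

#' @export
print.cmrf_parameter_maps <- function(x, ...) {
  fg <- !x$background
  cat(sprintf(
    "Parameter maps %d x %d: T1 %.0f-%.0f ms, T2 %.0f-%.0f ms (%d tissue voxels)\n",
    nrow(x$t1_map), ncol(x$t1_map), min(x$t1_map[fg]), max(x$t1_map[fg]),
    min(x$t2_map[fg]), max(x$t2_map[fg]), sum(fg)))
  invisible(x)
}

#' Match spatial basis images to a compressed dictionary
#'
#' Dot-product matching performed directly in the rank-k subspace: each
#' voxel's basis coefficient vector is compared against the rows of the
#' SVD-compressed dictionary D_k = D V_k.
#'
#' @param x_k Basis-image array (n_y x n_x x k).
#' @param D_k Compressed dictionary (p x k), from [compress_dictionary()].
#' @param entries Dictionary entry table (data.frame t1_ms, t2_ms).
#' @return A `cmrf_parameter_maps` object.
#' @export
match_compressed <- function(x_k, D_k, entries) {
  dims <- dim(x_k)[1:2]
  X <- matrix(x_k, prod(dims), dim(x_k)[3])
  match_time_series(X, D_k, entries, dims)
}

#' Configuration for the SLLR subspace reconstruction
#'
#' Regularization weights are relative to the maximum magnitude of the
#' initial (adjoint) basis images; the Charbonnier smoothing epsilon is
#' relative to the same scale.
#'
#' @param lambda_llr Locally-low-rank weight (default 0.02).
#' @param lambda_wav l1-wavelet weight (default 0.005).
#' @param patch Patch side for the locally-low-rank term (default 8).
#' @param n_iters Nonlinear conjugate-gradient iterations (default 25).
#' @param smoothing_eps Relative Charbonnier epsilon (default 1e-6).
#' @param wavelet_levels Decomposition levels (default 3).
#' @return An object of class `cmrf_sllr_config`.
#' @export
sllr_config <- function(lambda_llr = 0.02, lambda_wav = 0.005, patch = 8L,
                        n_iters = 25L, smoothing_eps = 1e-6,
                        wavelet_levels = 3L) {
  structure(list(lambda_llr = lambda_llr, lambda_wav = lambda_wav,
                 patch = as.integer(patch), n_iters = as.integer(n_iters),
                 smoothing_eps = smoothing_eps,
                 wavelet_levels = as.integer(wavelet_levels)),
            class = "cmrf_sllr_config")
}

charbonnier <- function(v, eps) sqrt(Mod(v)^2 + eps^2) - eps

# smoothed nuclear norm of patch matrices and its gradient
llr_penalty <- function(x_k, patch, eps) {
  n_y <- dim(x_k)[1]; n_x <- dim(x_k)[2]; k <- dim(x_k)[3]
  G <- array(0 + 0i, dim = dim(x_k))
  val <- 0
  for (py in seq(1, n_y, by = patch)) {
    for (px in seq(1, n_x, by = patch)) {
      ys <- py:min(py + patch - 1, n_y)
      xs <- px:min(px + patch - 1, n_x)
      M <- matrix(x_k[ys, xs, ], length(ys) * length(xs), k)
      sv <- svd(M)
      val <- val + sum(sqrt(sv$d^2 + eps^2) - eps)
      gs <- sv$u %*% (sv$d / sqrt(sv$d^2 + eps^2) * Conj(t(sv$v)))
      G[ys, xs, ] <- G[ys, xs, ] + array(gs, c(length(ys), length(xs), k))
    }
  }
  list(value = val, grad = G)
}

wav_penalty <- function(x_k, levels, eps) {
  G <- array(0 + 0i, dim = dim(x_k))
  val <- 0
  for (j in seq_len(dim(x_k)[3])) {
    w <- dwt2(x_k[, , j], levels)
    val <- val + sum(charbonnier(w, eps))
    G[, , j] <- idwt2(w / sqrt(Mod(w)^2 + eps^2), levels)
  }
  list(value = val, grad = G)
}

#' Sparse and locally-low-rank (SLLR) subspace reconstruction
#'
#' Estimates rank-k spatial basis images by minimizing a data-consistency
#' term plus a locally-low-rank penalty on 8 x 8 patch matrices
#' (patch-pixels x k) and an l1 penalty on Daubechies-4 wavelet
#' coefficients, both Charbonnier-smoothed, using nonlinear conjugate
#' gradient (Polak-Ribiere) with Armijo backtracking line search.
#' Spiral data use the exact NUDFT encoding; GROG-gridded Cartesian data
#' use the masked FFT encoding.
#'
#' @param data A `cmrf_spiral_data` or `cmrf_cartesian_data` object.
#' @param subspace A [compute_subspace()] object.
#' @param csm Coil maps (required for spiral data; Cartesian data carry
#'   their own).
#' @param cfg An [sllr_config()].
#' @return List with `x_k` (basis-image array), `cost` (per-iteration
#'   objective values) and `scale` (intensity scale used for the weights).
#' @export
sllr_reconstruct <- function(data, subspace, csm = NULL,
                             cfg = sllr_config()) {
  V_k <- subspace$V_k
  if (inherits(data, "cmrf_cartesian_data")) {
    if (is.null(csm)) csm <- data$csm
    A <- function(x) cart_forward_op(x, csm, V_k, data$P, data$W)
    Ah <- function(y) cart_adjoint_op(y, csm, V_k, data$P, data$W)
    y <- data$y_cart
  } else {
    if (is.null(csm)) stop("coil maps are required for spiral data")
    A <- function(x) spiral_forward_op(x, csm, V_k, data$traj,
                                       data$full_sampling)
    Ah <- function(y) spiral_adjoint_op(y, csm, V_k, data$traj,
                                        data$full_sampling)
    y <- data$y
  }
  x <- Ah(y)
  scale <- max(Mod(x))
  x <- array(0 + 0i, dim = dim(x))
  lam1 <- cfg$lambda_llr * scale
  lam2 <- cfg$lambda_wav * scale
  eps <- cfg$smoothing_eps * max(scale, 1e-30)

  cost_parts <- function(x, r) {
    data_term <- 0.5 * sum(Mod(r)^2)
    p1 <- if (lam1 > 0) llr_penalty(x, cfg$patch, eps) else list(value = 0, grad = 0)
    p2 <- if (lam2 > 0) wav_penalty(x, cfg$wavelet_levels, eps) else list(value = 0, grad = 0)
    list(f = data_term + lam1 * p1$value + lam2 * p2$value,
         grad_pen = lam1 * p1$grad + lam2 * p2$grad)
  }

  r <- A(x) - y
  cp <- cost_parts(x, r)
  g <- Ah(r) + cp$grad_pen
  d <- -g
  cost <- numeric(cfg$n_iters)
  f_old <- cp$f
  g_old <- g
  fails <- 0L
  for (it in seq_len(cfg$n_iters)) {
    Ad <- A(d)
    denom <- sum(Mod(Ad)^2)
    alpha <- if (denom > 0) -Re(sum(Conj(g) * d)) / denom else 1
    ok <- FALSE
    slope <- Re(sum(Conj(g) * d))
    for (ls in 1:20) {
      x_new <- x + alpha * d
      r_new <- r + alpha * Ad
      cp_new <- cost_parts(x_new, r_new)
      if (cp_new$f <= f_old + 1e-4 * alpha * slope) { ok <- TRUE; break }
      alpha <- alpha * 0.5
    }
    if (!ok) {
      fails <- fails + 1L
      if (fails >= 5L)
        stop(sprintf("SLLR line search failed 5 times at iteration %d (cost %.4g)",
                     it, f_old))
      cost[it] <- f_old
      d <- -g   # restart steepest descent
      next
    }
    fails <- 0L
    x <- x_new; r <- r_new
    g <- Ah(r_new) + cp_new$grad_pen
    beta <- max(0, Re(sum(Conj(g) * (g - g_old))) / sum(Mod(g_old)^2))
    d <- -g + beta * d
    if (Re(sum(Conj(g) * d)) > 0) d <- -g
    g_old <- g
    f_old <- cp_new$f
    cost[it] <- cp_new$f
  }
  list(x_k = x, cost = cost, scale = scale)
}
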