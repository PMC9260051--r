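#' Self-calibration from the spiral MRF data
#'
#' Pools all frames' spiral samples (the temporal average of the multicoil
#' k-space data), grids a time-averaged image per coil with the exact
#' NUDFT adjoint using cell-count density weights, and transforms back with
#' an FFT to obtain Cartesian multicoil k-space. Returns the central
#' calibration block used for GROG weight calibration, together with coil
#' sensitivity maps estimated from the time-averaged coil images by the
#' adaptive combination method (principal eigenvector of the local coil
#' covariance, phase-referenced to coil 1).
#'
#' @param data A [simulate_acquisition()] object (or compatible container).
#' @param calib_region Side length of the central Cartesian calibration
#'   block (default 48, clamped to the matrix size).
#' @param window Adaptive-combination local window (odd, default 7).
#' @return List with `calib` (complex calib x calib x n_coils block),
#'   `csm` (a `cmrf_coil_maps`), and `coil_images` (time-averaged images).
#' @export
self_calibration <- function(data, calib_region = 48L, window = 7L) {
  n <- data$traj$matrix
  t_total <- dim(data$y)[1]
  n_coils <- dim(data$y)[2]
  if (t_total < data$traj$n_interleaves && !isTRUE(data$full_sampling))
    warning("fewer frames than interleaves: calibration may be aliased")
  calib_region <- as.integer(min(calib_region, n))
  coords <- do.call(rbind, lapply(seq_len(t_total), function(i)
    spiral_frame_coords(data$traj, i, data$full_sampling)))
  w <- density_weights(coords, n, "counts")
  coil_images <- array(0 + 0i, dim = c(n, n, n_coils))
  for (cc in seq_len(n_coils)) {
    s <- as.vector(t(data$y[, cc, , drop = TRUE]))
    coil_images[, , cc] <- nudft_adjoint(w * s, coords, n, n)
  }
  ksp <- array(0 + 0i, dim = c(n, n, n_coils))
  for (cc in seq_len(n_coils)) ksp[, , cc] <- ft2c(coil_images[, , cc])
  ctr <- n %/% 2 + 1
  lo <- ctr - calib_region %/% 2
  idx <- seq(lo, length.out = calib_region)
  calib <- ksp[idx, idx, , drop = FALSE]
  csm <- adaptive_combine(coil_images, window)
  list(calib = calib, csm = csm, coil_images = coil_images)
}

# adaptive combination: dominant eigenvector of the local coil covariance
adaptive_combine <- function(coil_images, window = 7L) {
  n_y <- dim(coil_images)[1]; n_x <- dim(coil_images)[2]
  n_coils <- dim(coil_images)[3]
  if (n_coils == 1L) {
    S <- array(coil_images[, , 1] / pmax(Mod(coil_images[, , 1]), 1e-30),
               dim = c(n_y, n_x, 1))
    return(structure(list(S = S, n_coils = 1L), class = "cmrf_coil_maps"))
  }
  box <- function(m) {   # local window sum with zero padding
    h <- window %/% 2
    p <- matrix(0 + 0i, n_y + 2 * h, n_x + 2 * h)
    p[h + seq_len(n_y), h + seq_len(n_x)] <- m
    cs <- rbind(0 + 0i, apply(p, 2, cumsum))
    colsum <- cs[(window + 1):(n_y + 2 * h + 1), , drop = FALSE] -
      cs[1:(n_y + 2 * h + 1 - window), , drop = FALSE]
    cs2 <- cbind(0 + 0i, t(apply(colsum, 1, cumsum)))
    cs2[, (window + 1):(n_x + 2 * h + 1), drop = FALSE] -
      cs2[, 1:(n_x + 2 * h + 1 - window), drop = FALSE]
  }
  R <- vector("list", n_coils * n_coils)
  dim(R) <- c(n_coils, n_coils)
  for (a in seq_len(n_coils)) for (b in seq_len(a)) {
    R[[a, b]] <- box(coil_images[, , a] * Conj(coil_images[, , b]))
    if (a != b) R[[b, a]] <- Conj(R[[a, b]])
  }
  # power iteration across all voxels simultaneously
  v <- lapply(seq_len(n_coils), function(cc) coil_images[, , cc])
  for (it in 1:12) {
    nv <- lapply(seq_len(n_coils), function(a)
      Reduce(`+`, lapply(seq_len(n_coils), function(b) R[[a, b]] * v[[b]])))
    nrm <- sqrt(Reduce(`+`, lapply(nv, function(m) Mod(m)^2)))
    v <- lapply(nv, function(m) m / pmax(nrm, 1e-30))
  }
  ref <- v[[1]] / pmax(Mod(v[[1]]), 1e-30)
  S <- array(0 + 0i, dim = c(n_y, n_x, n_coils))
  for (cc in seq_len(n_coils)) S[, , cc] <- v[[cc]] * Conj(ref)
  structure(list(S = S, n_coils = n_coils), class = "cmrf_coil_maps")
}

#' Calibrate GROG unit-shift weight matrices
#'
#' Solves, in the least-squares sense, for the coil-coupling matrices G_x
#' and G_y that map each multicoil k-space column of the fully sampled
#' calibration block to its +1-cell neighbor along k_x and k_y.
#'
#' @param calib Complex calibration block (n_ky x n_kx x n_coils), fully
#'   sampled.
#' @return An object of class `cmrf_grog_ops` with complex
#'   n_coils x n_coils matrices `G_x`, `G_y` and the calibration size.
#' @export
calibrate_grog <- function(calib) {
  d <- dim(calib)
  n_coils <- d[3]
  unfold <- function(src_idx, tgt_idx, along) {
    if (along == "x") {
      S <- matrix(aperm(calib[, src_idx, , drop = FALSE], c(3, 1, 2)),
                  n_coils)
      T <- matrix(aperm(calib[, tgt_idx, , drop = FALSE], c(3, 1, 2)),
                  n_coils)
    } else {
      S <- matrix(aperm(calib[src_idx, , , drop = FALSE], c(3, 1, 2)),
                  n_coils)
      T <- matrix(aperm(calib[tgt_idx, , , drop = FALSE], c(3, 1, 2)),
                  n_coils)
    }
    list(S = S, T = T)
  }
  solve_g <- function(S, T) {
    A <- S %*% Conj(t(S))
    scale <- Re(sum(diag(A))) / nrow(A)
    lam <- 1e-9 * scale
    if (rcond(A) < 1e-12) {
      warning("rank-deficient GROG calibration; using regularized solve")
      lam <- 1e-6 * scale
    }
    T %*% Conj(t(S)) %*% solve(A + lam * diag(nrow(A)))
  }
  ux <- unfold(seq_len(d[2] - 1), seq_len(d[2] - 1) + 1L, "x")
  uy <- unfold(seq_len(d[1] - 1), seq_len(d[1] - 1) + 1L, "y")
  structure(list(G_x = solve_g(ux$S, ux$T), G_y = solve_g(uy$S, uy$T),
                 calib_region = d[1], n_coils = n_coils),
            class = "cmrf_grog_ops")
}

#' Fractional power of a GROG shift operator
#'
#' Computes G^delta through the eigendecomposition (principal branch of
#' the eigenvalue logarithm), the standard GROG mechanism for shifting
#' samples by a fraction of a grid cell.
#'
#' @param G Complex square matrix (unit-shift operator).
#' @param delta Shift fraction, |delta| <= 0.5 for gridding use (any real
#'   value is accepted; delta = 1 reproduces G, delta = 0 the identity).
#' @return Complex matrix G^delta.
#' @export
fractional_shift <- function(G, delta) {
  e <- eigen(G)
  if (rcond(e$vectors) < 1e-12) {
    warning("nearly defective GROG operator; perturbing before eigen power")
    e <- eigen(G + 1e-10 * mean(Mod(diag(G))) * diag(nrow(G)))
  }
  e$vectors %*% (exp(delta * log(e$values)) * solve(e$vectors))
}

#' Shift spiral MRF samples onto the Cartesian grid (GROG gridding)
#'
#' Every spiral sample is moved to its nearest integer grid cell (ties
#' rounded toward the negative index) by applying fractional powers of the
#' calibrated unit-shift operators, first along k_x then along k_y.
#' Samples landing in the same cell within a frame are averaged. The
#' density compensation function W is derived from the number of spiral
#' points (across the whole scan geometry) shifted into each cell:
#' W = 1/sqrt(count) on covered cells, normalized to a maximum of one,
#' which equalizes the per-cell energy contributed to the squared training
#' loss; every frame is multiplied by the same W. Binary masks P_i record
#' the cells sampled at each frame.
#'
#' @param data A [simulate_acquisition()] object.
#' @param ops [calibrate_grog()] operators.
#' @param csm Coil maps to attach (e.g. from [self_calibration()]).
#' @return An object of class `cmrf_cartesian_data`: `y_cart` (complex
#'   t x n_coils x n x n, density-compensated), `P` (logical t x n x n),
#'   `W` (n x n), `csm`, `schedule`, `rhythm`.
#' @export
grog_grid <- function(data, ops, csm = NULL) {
  n <- data$traj$matrix
  half <- n %/% 2
  t_total <- dim(data$y)[1]
  n_coils <- dim(data$y)[2]
  ex <- eigen(ops$G_x); ey <- eigen(ops$G_y)
  exi <- solve(ex$vectors); eyi <- solve(ey$vectors)
  llx <- log(ex$values); lly <- log(ey$values)

  y_cart <- array(0 + 0i, dim = c(t_total, n_coils, n, n))
  P <- array(FALSE, dim = c(t_total, n, n))
  counts <- matrix(0, n, n)
  for (i in seq_len(t_total)) {
    co <- spiral_frame_coords(data$traj, i, data$full_sampling)
    cell <- nearest_cell(co, n)
    dx <- cell[, 1] - co[, 1]
    dy <- cell[, 2] - co[, 2]
    Y <- matrix(data$y[i, , ], nrow = n_coils)              # n_coils x m
    Y <- ex$vectors %*% ((exi %*% Y) * exp(outer(llx, dx)))
    Y <- ey$vectors %*% ((eyi %*% Y) * exp(outer(lly, dy)))
    iy <- cell[, 2] + half + 1L
    ix <- cell[, 1] + half + 1L
    lin <- iy + (ix - 1L) * n
    hits <- rowsum(rep(1, length(lin)), lin)
    acc_re <- rowsum(t(Re(Y)), lin)
    acc_im <- rowsum(t(Im(Y)), lin)
    cells_lin <- as.integer(rownames(hits))
    avg <- (acc_re + 1i * acc_im) / as.vector(hits)
    frame <- matrix(0 + 0i, n * n, n_coils)
    frame[cells_lin, ] <- avg
    y_cart[i, , , ] <- t(frame)
    mask <- matrix(FALSE, n, n)
    mask[cells_lin] <- TRUE
    P[i, , ] <- mask
    counts[cells_lin] <- counts[cells_lin] + as.vector(hits)
  }
  W <- matrix(0, n, n)
  covered <- counts > 0
  W[covered] <- 1 / sqrt(counts[covered])
  W <- W / max(W)
  for (i in seq_len(t_total)) {
    for (cc in seq_len(n_coils)) {
      y_cart[i, cc, , ] <- y_cart[i, cc, , ] * W
    }
  }
  structure(list(y_cart = y_cart, P = P, W = W, csm = csm,
                 schedule = data$schedule, rhythm = data$rhythm,
                 matrix = n, noise_sigma = data$noise_sigma),
            class = "cmrf_cartesian_data")
}

#' @export
print.cmrf_cartesian_data <- function(x, ...) {
  d <- dim(x$y_cart)
  cat(sprintf("Cartesian (GROG) MRF data: %d frames x %d coils x %d x %d\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
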