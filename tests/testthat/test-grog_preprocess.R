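test_that("self-calibration extracts the central block and coil maps", {
  st <- fx_setup32()
  cal <- st$cal
  expect_identical(dim(cal$calib), c(32L, 32L, 8L))  # clamped to matrix
  cal48 <- self_calibration(st$acq, calib_region = 24L)
  expect_identical(dim(cal48$calib), c(24L, 24L, 8L))

  # estimated maps recover the simulated ones up to scale/reference phase
  S_est <- cal$csm$S; S_true <- st$csm_true$S
  supp <- which(st$fg)
  n <- st$n
  num <- den <- 0
  for (v in supp) {
    iy <- (v - 1) %% n + 1; ix <- (v - 1) %/% n + 1
    a <- S_est[iy, ix, ]; b <- S_true[iy, ix, ]
    num <- num + Mod(sum(Conj(a) * b))
    den <- den + sqrt(sum(Mod(a)^2)) * sqrt(sum(Mod(b)^2))
  }
  expect_gt(num / den, 0.98)
})

test_that("a single uniform coil yields a unit sensitivity estimate", {
  st <- fx_setup32()
  acq1 <- simulate_acquisition(st$phantom, fx_schedule_5hb(),
                               make_coil_maps(st$n, st$n, 1),
                               st$traj, noise_pct = 0, seed = 1)
  cal <- self_calibration(acq1)
  mags <- Mod(cal$csm$S[, , 1])[st$fg]
  expect_true(all(abs(mags - 1) < 0.02))
})

test_that("GROG calibration solves the unit-shift relations", {
  st <- fx_setup32()
  ops <- calibrate_grog(st$cal$calib)
  expect_identical(dim(ops$G_x), c(8L, 8L))
  # inverse contract on calibration columns
  calib <- st$cal$calib
  S <- matrix(aperm(calib[, 1:31, , drop = FALSE], c(3, 1, 2)), 8)
  moved <- solve(ops$G_x) %*% (ops$G_x %*% S)
  expect_lt(max(Mod(moved - S)) / max(Mod(S)), 1e-6)
  # prediction of the +1-cell neighbors: with idealized smooth synthetic
  # coil profiles the coil basis spans unit shifts only approximately, so
  # the operator is required to clearly beat the no-shift baseline rather
  # than to meet a fixed small residual
  src <- matrix(aperm(calib[, 1:31, , drop = FALSE], c(3, 1, 2)), 8)
  tgt <- matrix(aperm(calib[, 2:32, , drop = FALSE], c(3, 1, 2)), 8)
  err_g <- sqrt(sum(Mod(ops$G_x %*% src - tgt)^2) / sum(Mod(tgt)^2))
  err_id <- sqrt(sum(Mod(src - tgt)^2) / sum(Mod(tgt)^2))
  expect_lt(err_g, 0.6 * err_id)
  expect_lt(err_g, 0.7)
})

test_that("single-coil GROG weight reduces to the Fourier shift phase", {
  # delta-like object at a known offset: the one-cell shift operator is the
  # scalar exp(-2*pi*1i*x0/n) by the shift theorem
  n <- 32
  x0 <- 3
  img <- matrix(0, n, n)
  img[n / 2 + 1 + 1, n / 2 + 1 + x0] <- 1   # offset x0 in kx-conjugate axis
  K <- cmrf:::ft2c(img + 0i)
  calib <- array(K, c(n, n, 1))
  ops <- calibrate_grog(calib)
  expect_equal(drop(ops$G_x), exp(-2i * pi * x0 / n), tolerance = 1e-6)
})

test_that("fractional shift powers compose and hit their endpoints", {
  st <- fx_setup32()
  G <- calibrate_grog(st$cal$calib)$G_x
  expect_equal(fractional_shift(G, 0), diag(8) + 0i, tolerance = 1e-10)
  expect_equal(fractional_shift(G, 1), G, tolerance = 1e-8)
  comp <- fractional_shift(G, 0.3) %*% fractional_shift(G, 0.7)
  expect_lt(max(Mod(comp - G)) / max(Mod(G)), 1e-6)
})

test_that("gridding fills the masks and leaves on-grid samples unchanged", {
  st <- fx_setup32()
  ops <- calibrate_grog(st$cal$calib)
  cart <- grog_grid(st$acq, ops, st$cal$csm)
  n <- st$n
  # per-frame mask size equals the number of distinct target cells
  for (i in c(1L, 70L)) {
    co <- spiral_frame_coords(st$traj, i)
    cells <- unique(as.data.frame(cmrf:::nearest_cell(co, n)))
    expect_identical(sum(cart$P[i, , ]), nrow(cells))
  }
  # W is one map for all frames, supported on the union of masks
  union_mask <- apply(cart$P, c(2, 3), any)
  expect_true(all((cart$W > 0) == union_mask))
  expect_equal(max(cart$W), 1)
  # a full golden-angle cycle covers the k-space disc
  half <- n / 2
  ky <- matrix(rep(seq(-half, half - 1), n), n, n)
  kx <- t(ky)
  disc <- sqrt(kx^2 + ky^2) <= 0.9 * half
  expect_gt(mean(union_mask[disc]), 0.99)

  # integer-coordinate samples pass through the delta = 0 path unchanged
  traj0 <- st$traj
  traj0$base <- cbind(kx = c(0, 3, -5, 7), ky = c(0, 2, -4, -6))
  traj0$n_samples <- 4L
  traj0$rotation_per_tr_deg <- 0
  acq0 <- st$acq
  acq0$y <- st$acq$y[1:2, , 1:4, drop = FALSE]
  acq0$traj <- traj0
  sch2 <- acq0$schedule
  cart0 <- grog_grid(acq0, ops, st$cal$csm)
  for (s in 1:4) {
    iy <- traj0$base[s, "ky"] + half + 1
    ix <- traj0$base[s, "kx"] + half + 1
    got <- cart0$y_cart[1, , iy, ix] / cart0$W[iy, ix]
    expect_equal(got, st$acq$y[1, , s], tolerance = 1e-8)
  }
})

test_that("GROG-gridded reconstruction agrees with the NUDFT reference", {
  # static fully-sampled object: adjoint from GROG cells vs exact NUDFT
  st <- fx_setup32()
  n <- st$n
  ops <- calibrate_grog(st$cal$calib)
  cart <- grog_grid(st$acq, ops, st$cal$csm)
  # time-averaged image from GROG cells vs the NUDFT time-average
  n_fr <- dim(cart$y_cart)[1]
  rss <- matrix(0, n, n)
  img_grog <- matrix(0 + 0i, n, n)
  for (cc in 1:8) {
    acc <- matrix(0 + 0i, n, n)
    for (i in seq_len(n_fr)) acc <- acc + cart$y_cart[i, cc, , ]
    img_c <- cmrf:::ift2c(acc)
    img_grog <- img_grog + Conj(cart$csm$S[, , cc]) * img_c
  }
  ref <- st$cal$coil_images
  img_ref <- matrix(0 + 0i, n, n)
  for (cc in 1:8) img_ref <- img_ref + Conj(cart$csm$S[, , cc]) * ref[, , cc]
  m <- Mod(img_grog[st$fg]); r <- Mod(img_ref[st$fg])
  expect_gt(stats::cor(m, r), 0.98)
})
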