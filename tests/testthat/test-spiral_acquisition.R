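test_that("spiral trajectory matches its design constraints", {
  tr <- make_spiral(matrix = 64, n_interleaves = 48, dwell_us = 10)
  expect_identical(tr$n_interleaves, 48L)
  expect_equal(tr$rotation_per_tr_deg, 111.246)
  kmax <- max(sqrt(rowSums(tr$base^2)))
  expect_lt(abs(kmax - 32) / 32, 0.005)
  expect_equal(tr$base[1, ], c(kx = 0, ky = 0))   # DC sample leads
  expect_error(make_spiral(n_interleaves = 0))
})

test_that("golden-angle rotations never repeat over 705 TRs", {
  tr <- make_spiral(matrix = 64, dwell_us = 10)
  ang <- ((seq_len(705) - 1) * tr$rotation_per_tr_deg) %% 360
  d <- abs(outer(ang, ang, "-"))
  d <- pmin(d, 360 - d)
  expect_gt(min(d[upper.tri(d)]), 0.01)
})

test_that("the NUDFT satisfies the operator contracts", {
  set.seed(42)
  img <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  co <- cbind(runif(40, -4, 3.49), runif(40, -4, 3.49))
  yy <- complex(real = rnorm(40), imaginary = rnorm(40))
  lhs <- sum(nudft_forward(img, co) * Conj(yy))
  rhs <- sum(img * Conj(nudft_adjoint(yy, co, 8, 8)))
  expect_lt(Mod(lhs - rhs) / (cmrf:::fnorm(img) * cmrf:::fnorm(yy)), 1e-6)

  # centered unit impulse: all samples have magnitude 1 (up to 1/sqrt(N))
  imp <- matrix(0 + 0i, 8, 8); imp[5, 5] <- 1
  expect_equal(Mod(nudft_forward(imp, co)) * 8, rep(1, 40), tolerance = 1e-9)

  expect_error(nudft_forward(img, cbind(10, 0)), "band")
})

test_that("the NUDFT agrees with an explicit Fourier sum", {
  set.seed(7)
  img <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  co <- cbind(runif(25, -4, 3.49), runif(25, -4, 3.49))
  fast <- nudft_forward(img, co)
  slow <- brute_nudft(img, co)
  expect_lt(max(Mod(fast - slow)) / max(Mod(slow)), 1e-6)
})

test_that("the centered FFT convention is orthonormal and consistent", {
  set.seed(1)
  x <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16)
  X <- cmrf:::ft2c(x)
  expect_equal(cmrf:::fnorm(X), cmrf:::fnorm(x), tolerance = 1e-12)
  expect_equal(cmrf:::ift2c(X), x, tolerance = 1e-12)
  # integer-coordinate NUDFT equals the centered FFT
  kk <- as.matrix(expand.grid(kx = -8:7, ky = -8:7))
  y <- nudft_forward(x, kk)
  expect_equal(y, X[cbind(kk[, 2] + 9, kk[, 1] + 9)], tolerance = 1e-9)
})

test_that("the full interleaf set is Nyquist-complete for bandlimited images", {
  n <- 32
  tr <- make_spiral(matrix = n, n_interleaves = 48, dwell_us = 20)
  x <- seq(-1, 1, length.out = n)
  X <- matrix(rep(x, each = n), n, n); Y <- matrix(rep(x, n), n, n)
  img <- exp(-((X - 0.2)^2 + Y^2) / 0.08) +
    0.6i * exp(-((X + 0.3)^2 + (Y - 0.2)^2) / 0.15)
  co <- spiral_frame_coords(tr, 1, full_sampling = TRUE)
  y <- nudft_forward(img, co)
  # ramp weights are the analytic density for the uniform-angle union
  w <- density_weights(co, n, "ramp")
  rec <- nudft_adjoint(w * y, co, n, n)
  al <- sum(Conj(rec) * img) / sum(Mod(rec)^2)
  rel <- sqrt(sum(Mod(al * rec - img)^2) / sum(Mod(img)^2))
  expect_lt(rel, 0.05)
})

test_that("simulated acquisitions are reproducible and correctly sized", {
  st <- fx_setup32()
  expect_identical(dim(st$acq$y)[1], 140L)
  a1 <- simulate_acquisition(st$phantom, fx_schedule_5hb(), st$csm_true,
                             st$traj, noise_pct = 0, seed = 1)
  a2 <- simulate_acquisition(st$phantom, fx_schedule_5hb(), st$csm_true,
                             st$traj, noise_pct = 0, seed = 2)
  expect_identical(a1$y, a2$y)     # no noise: seed independent
  expect_error(simulate_acquisition(st$phantom, fx_schedule_5hb(),
                                    st$csm_true, st$traj, noise_pct = -1))
})

test_that("k-space noise matches the requested standard deviation", {
  st <- fx_setup32()
  ph0 <- st$phantom
  ph0$m0_map[] <- 0 + 0i             # empty object: pure noise acquisition
  acq <- simulate_acquisition(ph0, fx_schedule_5hb(), st$csm_true, st$traj,
                              noise_sigma = 0.37, seed = 9)
  samp <- c(Re(acq$y), Im(acq$y))
  expect_gt(length(samp), 1e5)
  expect_lt(abs(sd(samp) - 0.37) / 0.37, 0.05)
})
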