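# 32 x 32 GROG-gridded data shared by the DIP training tests; a depth-4
# network is used at this matrix size (the bottom of a depth-5 net would
# be a single pixel)
fx_cart32 <- function() {
  fx("cart32", {
    st <- fx_setup32()
    grog_grid(st$acq, calibrate_grog(st$cal$calib), st$cal$csm)
  })
}

dip_cfg32 <- function(n_iters, ...) {
  dip_config(n_iters = n_iters, irn = irn_config(channels = rep(48L, 4)),
             ...)
}

test_that("the Cartesian forward model matches the explicit loop nest", {
  set.seed(5)
  n <- 8L; k <- 3L; n_coils <- 4L
  x_k <- array(complex(real = rnorm(n * n * k),
                       imaginary = rnorm(n * n * k)), c(n, n, k))
  csm <- list(S = array(complex(real = rnorm(n * n * n_coils),
                                imaginary = rnorm(n * n * n_coils)),
                        c(n, n, n_coils)))
  V <- matrix(complex(real = rnorm(6 * k), imaginary = rnorm(6 * k)), 6, k)
  sub <- list(V_k = V, k = k)
  P_i <- matrix(runif(n * n) < 0.5, n, n)
  W <- matrix(runif(n * n), n, n)
  fast <- forward_model_frame(x_k, csm, sub, P_i, W, 4L)
  slow <- brute_forward_frame(x_k, csm, V, P_i, W, 4L)
  expect_lt(max(Mod(fast - slow)) / max(Mod(slow)), 1e-6)

  # linearity
  expect_equal(forward_model_frame(x_k * (2 - 1i), csm, sub, P_i, W, 2L),
               forward_model_frame(x_k, csm, sub, P_i, W, 2L) * (2 - 1i),
               tolerance = 1e-10)
  expect_error(forward_model_frame(x_k, csm, sub, P_i, W, 7L), "range")
})

test_that("identity subspace and trivial weights reduce to a plain FFT", {
  set.seed(6)
  n <- 8L
  t_len <- 3L
  x_k <- array(complex(real = rnorm(n * n * t_len),
                       imaginary = rnorm(n * n * t_len)), c(n, n, t_len))
  csm <- list(S = array(1 + 0i, c(n, n, 1)))
  sub <- list(V_k = diag(t_len) + 0i, k = t_len)
  ones <- matrix(TRUE, n, n)
  out <- forward_model_frame(x_k, csm, sub, ones, matrix(1, n, n), 2L)
  expect_equal(out[, , 1], cmrf:::ft2c(x_k[, , 2]), tolerance = 1e-12)
})

test_that("the compiled training loop shares the package FFT convention", {
  set.seed(2)
  x <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16)
  expect_equal(cmrf:::ctr_fft2_cpp(x), cmrf:::ft2c(x), tolerance = 1e-12)
  expect_equal(cmrf:::ctr_ifft2_cpp(x), cmrf:::ift2c(x), tolerance = 1e-12)
})

test_that("the convolution kernels agree with an R reference", {
  for (stride in 1:2) {
    r <- cmrf:::conv3_test_cpp(5L, 6L, 8L, 3L, 4L, stride)
    nbr <- r$nbr; X <- r$X; W <- r$W
    no <- nrow(nbr); cin <- ncol(X)
    Yref <- matrix(rep(r$b, each = no), no, ncol(W))
    dWref <- matrix(0, 9 * cin, ncol(W))
    dXref <- matrix(0, nrow(X), cin)
    for (j in 1:9) {
      idx <- nbr[, j]; ok <- idx >= 0
      Xs <- matrix(0, no, cin)
      Xs[ok, ] <- X[idx[ok] + 1, , drop = FALSE]
      Wj <- W[((j - 1) * cin + 1):(j * cin), , drop = FALSE]
      Yref <- Yref + Xs %*% Wj
      dWref[((j - 1) * cin + 1):(j * cin), ] <- t(Xs) %*% r$dY
      G <- r$dY %*% t(Wj)
      for (i in which(ok)) dXref[idx[i] + 1, ] <- dXref[idx[i] + 1, ] + G[i, ]
    }
    expect_lt(max(abs(r$Y - Yref)), 1e-4)
    expect_lt(max(abs(r$dW - dWref)), 1e-4)
    expect_lt(max(abs(r$dX - dXref)), 1e-4)
  }
})

test_that("the loss-1 gradient passes a finite-difference check", {
  err <- cmrf:::unet_gradcheck_cpp(3L, 8L, 8L, 3L, 2L, c(4L, 5L), 2L, 6L,
                                   300L, 1e-3)
  expect_lt(err, 0.05)
})

test_that("DIP training is reproducible and structurally sound", {
  cart <- fx_cart32()
  sub <- fx_subspace_small()
  fgn <- fx_fgn_5hb()
  r1 <- dip_reconstruct(cart, sub, fgn, dip_cfg32(300, seed = 5))
  r2 <- dip_reconstruct(cart, sub, fgn, dip_cfg32(300, seed = 5))
  expect_identical(r1$loss1, r2$loss1)
  expect_identical(r1$loss2, r2$loss2)
  expect_identical(r1$maps$t1_map, r2$maps$t1_map)
  expect_identical(r1$z_hash, r2$z_hash)       # fixed input tensor
  r3 <- dip_reconstruct(cart, sub, fgn, dip_cfg32(300, seed = 6))
  expect_false(identical(r1$loss1, r3$loss1))

  expect_length(r1$loss1, 300L)
  expect_length(r1$loss2, 300L)
  # smoothed loss 1 decreases over training
  expect_lt(mean(utils::tail(r1$loss1, 50)), mean(utils::head(r1$loss1, 50)))
  # PEN outputs respect the bounded activations
  expect_true(all(r1$maps$t1_map >= 50 & r1$maps$t1_map <= 3000))
  expect_true(all(r1$maps$t2_map >= 5 & r1$maps$t2_map <= 1000))
  expect_true(all(is.finite(Mod(r1$maps$m0_map))))
  expect_identical(dim(r1$x_k), c(32L, 32L, 5L))
})

test_that("a schedule/FGN mismatch is rejected", {
  cart <- fx_cart32()
  sub <- fx_subspace_small()
  sch15 <- fx_schedule_15hb()
  fgn_bad <- structure(list(t = 705L, n_rr = 14L, rr_norm = 2000,
                            weights = list()), class = "cmrf_fgn")
  expect_error(dip_reconstruct(cart, sub, fgn_bad), "match")
})
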