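test_that("dictionary matching recovers exact rows with the right scale", {
  d <- fx_dict_small()
  X <- d$D[c(10L, 250L, 999L), , drop = FALSE]
  X[2, ] <- (2 + 0i) * X[2, ]
  X <- rbind(X, 0 + 0i)                       # all-zero voxel -> background
  m <- cmrf:::match_time_series(X, d$D, d$entries, c(2L, 2L))
  expect_equal(as.vector(m$t1_map)[1:3],
               d$entries$t1_ms[c(10L, 250L, 999L)])
  expect_equal(as.vector(m$t2_map)[1:3],
               d$entries$t2_ms[c(10L, 250L, 999L)])
  expect_equal(as.vector(m$m0_map)[1:2], c(1 + 0i, 2 + 0i), tolerance = 1e-8)
  expect_true(as.vector(m$background)[4])
  expect_equal(as.vector(m$m0_map)[4], 0 + 0i)
})

test_that("compressed matching is self-consistent and flags empty voxels", {
  d <- fx_dict_small()
  sub <- fx_subspace_small()
  D_k <- compress_dictionary(d, sub)
  idx <- as.integer(round(seq(5, nrow(D_k) - 3, length.out = 4)))
  x_k <- array(D_k[idx, ], c(2, 2, 5))
  m <- match_compressed(x_k, D_k, d$entries)
  expect_equal(as.vector(m$t1_map), d$entries$t1_ms[idx])
  expect_equal(as.vector(m$t2_map), d$entries$t2_ms[idx])
  x0 <- array(0 + 0i, c(1, 1, 5))
  m0 <- match_compressed(x0, D_k, d$entries)
  expect_true(m0$background[1, 1])
})

test_that("compressed and full-time matching agree on noiseless voxels", {
  d <- fx_dict_small()
  sub <- fx_subspace_small()
  D_k <- compress_dictionary(d, sub)
  set.seed(4)
  idx <- sample(nrow(d$D), 300L)
  X <- d$D[idx, , drop = FALSE]
  m_full <- cmrf:::match_time_series(X, d$D, d$entries, c(300L, 1L))
  m_comp <- cmrf:::match_time_series(X %*% sub$V_k, D_k, d$entries,
                                     c(300L, 1L))
  agree <- mean(m_full$t1_map == m_comp$t1_map &
                  m_full$t2_map == m_comp$t2_map)
  expect_gte(agree, 0.99)
})

test_that("the Daubechies-4 wavelet transform is orthonormal", {
  set.seed(2)
  x <- matrix(complex(real = rnorm(1024), imaginary = rnorm(1024)), 32, 32)
  w <- cmrf:::dwt2(x, 3L)
  expect_equal(cmrf:::fnorm(w), cmrf:::fnorm(x), tolerance = 1e-10)
  expect_equal(cmrf:::idwt2(w, 3L), x, tolerance = 1e-10)
})

test_that("unregularized SLLR converges to the least-squares solution", {
  # short 2-heartbeat scan, fully sampled, noiseless, single flat coil:
  # the operator is unitary up to the subspace projection, so 25 NCG
  # iterations must reach the projection of the true image series
  sch2 <- build_schedule(sequence_params(n_heartbeats = 2L, window_ms = 50))
  st <- fx_setup32()
  dict2 <- build_dictionary(sch2, seq(200, 1800, 100), seq(20, 280, 20))
  sub2 <- compute_subspace(dict2, 8L)
  csm1 <- make_coil_maps(st$n, st$n, 1)
  # complete Cartesian sampling: the encoding operator is unitary, so the
  # conjugate-gradient iterations must reach the least-squares solution
  traj_cart <- st$traj
  grid <- as.matrix(expand.grid(kx = seq(-st$n / 2, st$n / 2 - 1),
                                ky = seq(-st$n / 2, st$n / 2 - 1)))
  traj_cart$base <- grid
  traj_cart$n_samples <- nrow(grid)
  traj_cart$n_interleaves <- 1L
  traj_cart$rotation_per_tr_deg <- 0
  acq <- simulate_acquisition(st$phantom, sch2, csm1,
                              traj_cart, noise_pct = 0, seed = 1,
                              full_sampling = TRUE)
  rec <- sllr_reconstruct(acq, sub2, csm1,
                          sllr_config(lambda_llr = 0, lambda_wav = 0,
                                      n_iters = 25L))
  sig <- cmrf:::phantom_fingerprints(st$phantom, sch2)
  x_true <- array(sig$voxel_signal %*% sub2$V_k, c(st$n, st$n, 8))
  rel <- cmrf:::fnorm(rec$x_k - x_true) / cmrf:::fnorm(x_true)
  expect_lt(rel, 0.02)
  expect_true(all(diff(rec$cost) <= 1e-8 * abs(rec$cost[1])))
})

test_that("SLLR with default weights improves on direct matching", {
  st <- fx_setup32()
  d <- fx_dict_small()
  sub <- fx_subspace_small()
  csm <- st$cal$csm
  m_dir <- direct_match(st$acq, d, csm)
  rec <- sllr_reconstruct(st$acq, sub, csm, sllr_config())
  m_sllr <- match_compressed(rec$x_k, compress_dictionary(d, sub),
                             d$entries)
  fg <- st$fg
  t1_dir <- nrmse(m_dir$t1_map, st$phantom$t1_map, fg)$value_pct
  t1_sllr <- nrmse(m_sllr$t1_map, st$phantom$t1_map, fg)$value_pct
  expect_lt(t1_sllr, t1_dir)
  expect_true(all(diff(rec$cost) <= 1e-8 * abs(rec$cost[1])))
})

test_that("SLLR output co-rotates with a global data phase", {
  st <- fx_setup32()
  sub <- fx_subspace_small()
  cfg <- sllr_config(n_iters = 4L)
  rec1 <- sllr_reconstruct(st$acq, sub, st$cal$csm, cfg)
  acq_rot <- st$acq
  acq_rot$y <- st$acq$y * exp(0.7i)
  rec2 <- sllr_reconstruct(acq_rot, sub, st$cal$csm, cfg)
  expect_equal(rec2$x_k, rec1$x_k * exp(0.7i), tolerance = 1e-6)
})
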