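test_that("zero flip angles yield an identically zero fingerprint", {
  s <- build_schedule(sequence_params(n_heartbeats = 5L, window_ms = 150,
                                      flip_min_deg = 0, flip_max_deg = 0))
  fp <- simulate_fingerprint(1000, 50, s)
  expect_equal(max(Mod(fp)), 0)
})

test_that("EPG matches the isochromat-summation oracle across the range", {
  s <- fx_schedule_5hb()
  t1s <- c(100, 1000, 2500)
  t2s <- c(20, 80, 300)
  for (t1 in t1s) {
    for (t2 in t2s) {
      if (t2 >= t1) next
      epg <- simulate_fingerprint(t1, t2, s)
      iso <- isochromat_fingerprint(t1, t2, s, n_iso = 256L)
      rel <- sqrt(sum(Mod(epg - iso)^2) / sum(Mod(iso)^2))
      expect_lt(rel, 0.01)
    }
  }
})

test_that("T2 preparation attenuates the signal by exp(-tau/T2)", {
  # single heartbeat, single excitation: signal with a T2 prep of duration
  # tau equals the unprepared signal scaled by exp(-tau/T2)
  flip <- pi / 6
  tau <- 50
  t2 <- 80
  base <- epg_simulate_cpp(1000, t2, flip, 1L, 5.4, 1.4,
                           0L, 0, numeric(0), 20L)
  prep <- epg_simulate_cpp(1000, t2, flip, 1L, 5.4, 1.4,
                           2L, tau, numeric(0), 20L)
  expect_equal(prep[1, 1], base[1, 1] * exp(-tau / t2), tolerance = 1e-10)
})

test_that("fingerprints depend on the RR intervals", {
  p <- sequence_params(n_heartbeats = 5L, window_ms = 150)
  f1 <- simulate_fingerprint(1000, 50, build_schedule(p, rep(850, 4)))
  rr <- c(850, 850, 1200, 850)
  f2 <- simulate_fingerprint(1000, 50, build_schedule(p, rr))
  expect_gt(max(Mod(f1 - f2)), 1e-5)
})

test_that("the default dictionary lands near 23,000 entries and is consistent", {
  # entry count from the grid definition (simulation not needed)
  grid <- expand.grid(t1 = default_t1_grid(), t2 = default_t2_grid())
  p <- sum(grid$t2 < grid$t1)
  expect_gte(p, 20000)
  expect_lte(p, 26000)

  d <- fx_dict_small()
  expect_false(any(d$entries$t2_ms >= d$entries$t1_ms))
  i <- 137L
  row <- simulate_fingerprint(d$entries$t1_ms[i], d$entries$t2_ms[i],
                              fx_schedule_5hb())
  expect_equal(drop(d$D[i, ]), row, tolerance = 1e-12)
})

test_that("the rank-k subspace obeys the SVD identities", {
  d <- fx_dict_small()
  sub <- fx_subspace_small()
  V <- sub$V_k
  expect_equal(max(Mod(Conj(t(V)) %*% V - diag(sub$k))), 0, tolerance = 1e-10)
  # projection error equals sqrt(1 - energy fraction)
  proj <- (d$D %*% V) %*% Conj(t(V))
  rel <- sqrt(sum(Mod(d$D - proj)^2) / sum(Mod(d$D)^2))
  expect_equal(rel, sqrt(1 - sub$energy_fraction), tolerance = 1e-8)

  # full-rank subspace reconstructs the dictionary exactly
  t_len <- ncol(d$D)
  sub_full <- compute_subspace(d, t_len)
  expect_equal(sub_full$energy_fraction, 1, tolerance = 1e-12)
  rec <- (d$D %*% sub_full$V_k) %*% Conj(t(sub_full$V_k))
  expect_lt(max(Mod(rec - d$D)), 1e-8)
  expect_error(compute_subspace(d, t_len + 1L))
})

test_that("dictionary compression is the subspace projection", {
  d <- fx_dict_small()
  sub <- fx_subspace_small()
  D_k <- compress_dictionary(d, sub)
  expect_identical(dim(D_k), c(nrow(d$D), 5L))
  # row norms cannot grow under projection
  expect_true(all(sqrt(rowSums(Mod(D_k)^2)) <=
                    sqrt(rowSums(Mod(d$D)^2)) + 1e-12))
  expect_equal(D_k, d$D %*% sub$V_k)
})
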