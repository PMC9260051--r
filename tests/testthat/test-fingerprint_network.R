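test_that("the pretrained FGN reproduces simulated fingerprints", {
  fgn <- fx_fgn_5hb()
  expect_identical(fgn$t, 140L)
  expect_identical(fgn$n_rr, 4L)
  # median relative l2 error over a fresh holdout below 2%
  expect_lt(fgn$holdout_median_rel_err, 0.02)

  sch <- fx_schedule_5hb()
  rhythm <- constant_rhythm(sch$params)
  fp <- fgn_forward(fgn, 1000, 50, rhythm)
  expect_length(fp, 140L)
  ref <- simulate_fingerprint(1000, 50, sch)
  ref <- ref / sqrt(sum(Mod(ref)^2))
  expect_lt(sqrt(sum(Mod(fp - ref)^2)), 0.02)
})

test_that("FGN evaluation is batched and permutation-equivariant", {
  fgn <- fx_fgn_5hb()
  rhythm <- constant_rhythm(fx_schedule_5hb()$params)
  t1 <- c(300, 800, 1400, 2200)
  t2 <- c(40, 60, 120, 250)
  batch <- fgn_forward(fgn, t1, t2, rhythm)
  expect_identical(dim(batch), c(4L, 140L))
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(fgn_forward(fgn, t1[perm], t2[perm], rhythm), batch[perm, ])
  expect_warning(fgn_forward(fgn, 5000, 50, rhythm), "range")
  expect_error(fgn_forward(fgn, 1000, 50, c(900, 900)), "heartbeat")
})

test_that("FGN pre-training is deterministic under a fixed seed", {
  sch <- fx_schedule_5hb()
  a <- pretrain_fgn(sch, n_train = 3000, epochs = 4, batch = 256,
                    seed = 21, tol = 1)
  b <- pretrain_fgn(sch, n_train = 3000, epochs = 4, batch = 256,
                    seed = 21, tol = 1)
  expect_identical(a$val_loss, b$val_loss)
  expect_identical(a$weights, b$weights)
})

test_that("an FGN-generated dictionary preserves the rank-5 energy", {
  fgn <- fx_fgn_5hb()
  sch <- fx_schedule_5hb()
  rhythm <- constant_rhythm(sch$params)
  d <- fgn_dictionary(fgn, rhythm)
  expect_gte(nrow(d$D), 20000)
  sub <- compute_subspace(d, 5L)
  # the surrogate must not dilute the low-rank structure: its dictionary
  # retains the same rank-5 energy as the simulator's (99.90% for this
  # 140-TR schedule) to within 0.1 percentage point
  sub_sim <- compute_subspace(build_dictionary(sch), 5L)
  expect_gt(sub$energy_fraction, 0.998)
  expect_gt(sub$energy_fraction, sub_sim$energy_fraction - 0.001)
})

test_that("FGN-based and simulator-based matching select the same entries", {
  fgn <- fx_fgn_5hb()
  sch <- fx_schedule_5hb()
  rhythm <- constant_rhythm(sch$params)
  # grid spacing must exceed the surrogate's ~1% fingerprint error for
  # entry-identical matching to be a meaningful check
  t1g <- seq(100, 2000, by = 200)
  t2g <- seq(20, 300, by = 50)
  d_sim <- build_dictionary(fx_schedule_5hb(), t1g, t2g)
  d_fgn <- fgn_dictionary(fgn, rhythm, t1_grid = t1g, t2_grid = t2g)
  set.seed(8)
  idx <- sample(nrow(d_sim$D), min(200L, nrow(d_sim$D)))
  X <- d_sim$D[idx, , drop = FALSE]
  m_sim <- cmrf:::match_time_series(X, d_sim$D, d_sim$entries,
                           c(length(idx), 1L))
  m_fgn <- cmrf:::match_time_series(X, d_fgn$D, d_fgn$entries,
                           c(length(idx), 1L))
  agree <- mean(m_sim$t1_map == m_fgn$t1_map &
                  m_sim$t2_map == m_fgn$t2_map)
  expect_gte(agree, 0.95)
})

test_that("FGN output is differentiable in its relaxation-time inputs", {
  fgn <- fx_fgn_5hb()
  rhythm <- constant_rhythm(fx_schedule_5hb()$params)
  h <- 0.5
  d <- (fgn_forward(fgn, 1000 + h, 50, rhythm) -
          fgn_forward(fgn, 1000 - h, 50, rhythm)) / (2 * h)
  expect_true(all(is.finite(Re(d)) & is.finite(Im(d))))
  expect_gt(max(Mod(d)), 0)
})
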