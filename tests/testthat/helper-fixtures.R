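# Shared fixtures, built once per test session and memoized.

fixture_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

fx_schedule_5hb <- function() {
  fx("schedule_5hb", build_schedule(
    sequence_params(n_heartbeats = 5L, window_ms = 150)))
}

fx_schedule_15hb <- function() {
  fx("schedule_15hb", build_schedule(sequence_params()))
}

# coarse dictionary over the physiological range (fast to simulate)
fx_dict_small <- function() {
  fx("dict_small", build_dictionary(fx_schedule_5hb(),
                                    t1_grid = seq(100, 2000, by = 50),
                                    t2_grid = seq(10, 300, by = 10)))
}

fx_subspace_small <- function() {
  fx("subspace_small", compute_subspace(fx_dict_small(), 5L))
}

# 32 x 32 acquisition setup used by the reconstruction tests
fx_setup32 <- function() {
  fx("setup32", {
    n <- 32L
    phantom <- make_cardiac_phantom(n, n, seed = 11L)
    csm <- make_coil_maps(n, n, 8L, seed = 11L)
    traj <- make_spiral(matrix = n, n_interleaves = 48L, dwell_us = 20)
    acq <- simulate_acquisition(phantom, fx_schedule_5hb(), csm, traj,
                                noise_pct = 0.1, seed = 11L)
    cal <- self_calibration(acq)
    list(n = n, phantom = phantom, csm_true = csm, traj = traj, acq = acq,
         cal = cal, fg = phantom$labels > 0L)
  })
}

# FGN shared by the DIP and acceptance tests (a notch above the default
# training budget; the surrogate's accuracy feeds the T2 checks)
fx_fgn_5hb <- function() {
  fx("fgn_5hb", pretrain_fgn(fx_schedule_5hb(), n_train = 60000L,
                             epochs = 60L, seed = 3L))
}
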