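test_that("images per heartbeat reproduces the published counts", {
  expect_identical(images_per_heartbeat(254, 5.4), 47L)
  expect_identical(images_per_heartbeat(200, 5.4), 37L)
  expect_identical(images_per_heartbeat(150, 5.4), 28L)
  expect_identical(images_per_heartbeat(100, 5.4), 19L)
  expect_identical(images_per_heartbeat(50, 5.4), 9L)
  expect_identical(images_per_heartbeat(5.4, 5.4), 1L)
  expect_error(images_per_heartbeat(0, 5.4), "positive")
  expect_error(images_per_heartbeat(150, -1), "positive")
})

test_that("schedules reproduce all published TR totals", {
  variants <- list(list(hb = 15L, win = 254, trs = 705L),
                   list(hb = 5L, win = 254, trs = 235L),
                   list(hb = 5L, win = 200, trs = 185L),
                   list(hb = 5L, win = 150, trs = 140L),
                   list(hb = 5L, win = 100, trs = 95L),
                   list(hb = 5L, win = 50, trs = 45L))
  for (v in variants) {
    s <- build_schedule(sequence_params(n_heartbeats = v$hb,
                                        window_ms = v$win))
    expect_identical(s$total_trs, v$trs)
  }
})

test_that("the preparation schedule cycles inversion/none/T2-preps", {
  s <- fx_schedule_15hb()
  pe <- s$prep_events
  expect_identical(sum(pe$kind == "inversion"), 3L)
  expect_identical(pe$kind[1:5], c("inversion", "none", "t2prep", "t2prep",
                                   "t2prep"))
  expect_equal(pe$duration_ms[1], 21)
  expect_equal(pe$duration_ms[3:5], c(30, 50, 80))
  # periodicity over the prep cycle
  cyc <- s$params$prep_cycle_length
  for (h in seq_len(nrow(pe) - cyc)) {
    expect_identical(pe$kind[h], pe$kind[h + cyc])
    expect_equal(pe$duration_ms[h], pe$duration_ms[h + cyc])
  }
})

test_that("flip-angle series respects the 4-25 degree range and truncation", {
  full <- flip_angle_series(47L)
  expect_length(full, 47L)
  expect_gte(min(full), 4)
  expect_lte(max(full), 25)
  expect_equal(min(full), 4)
  expect_equal(max(full), 25, tolerance = 1e-6)
  expect_identical(flip_angle_series(28L), full[1:28])
  expect_identical(flip_angle_series(1L), full[1])
  expect_error(flip_angle_series(0L))
})

test_that("schedules are pure functions of parameters and rhythm", {
  p <- sequence_params(n_heartbeats = 5L, window_ms = 150)
  r <- cardiac_rhythm(c(900, 850, 820, 880))
  expect_identical(build_schedule(p, r), build_schedule(p, r))
  expect_error(build_schedule(p, cardiac_rhythm(c(900, 850))), "RR")
})

test_that("schedule serialization round-trips through YAML and JSON", {
  s <- build_schedule(sequence_params(n_heartbeats = 5L, window_ms = 150),
                      cardiac_rhythm(c(900, 850, 820, 880)))
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_schedule(s, f)
    s2 <- read_schedule(f)
    expect_identical(s2$total_trs, s$total_trs)
    expect_equal(s2$flip_deg, s$flip_deg, tolerance = 1e-9)
    expect_equal(s2$rhythm$rr_intervals_ms, s$rhythm$rr_intervals_ms)
    expect_identical(s2$prep_events$kind, s$prep_events$kind)
    unlink(f)
  }
})
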