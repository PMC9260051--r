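#' Sequence parameters for the ECG-triggered cardiac MRF acquisition
#'
#' Describes the FISP cardiac MRF sequence: an ECG-triggered diastolic
#' acquisition window repeated every heartbeat, a constant TR/TE, variable
#' flip angles, and a cycling magnetization-preparation schedule
#' (inversion / no prep / T2 preparations).
#'
#' @param n_heartbeats Number of heartbeats (breathhold length), >= 1.
#' @param window_ms Acquisition window per heartbeat in ms.
#' @param tr_ms Repetition time in ms.
#' @param te_ms Echo time in ms; must be smaller than `tr_ms`.
#' @param flip_min_deg,flip_max_deg Range of the variable flip angles (deg).
#' @param inversion_delay_ms Delay between the inversion pulse and the first
#'   excitation of the heartbeat (ms).
#' @param t2prep_times_ms T2-preparation durations (ms) used in the prep
#'   cycle, one per T2-prep heartbeat.
#' @param prep_cycle_length Length of the preparation cycle in heartbeats.
#'   The cycle is: heartbeat 1 inversion, heartbeat 2 no preparation, then
#'   one T2 preparation per remaining heartbeat of the cycle.
#' @return An object of class `cmrf_sequence_params`.
#' @export
sequence_params <- function(n_heartbeats = 15L, window_ms = 254, tr_ms = 5.4,
                            te_ms = 1.4, flip_min_deg = 4, flip_max_deg = 25,
                            inversion_delay_ms = 21,
                            t2prep_times_ms = c(30, 50, 80),
                            prep_cycle_length = 5L) {
  if (n_heartbeats < 1) stop("n_heartbeats must be >= 1")
  if (tr_ms <= 0) stop("tr_ms must be positive")
  if (te_ms <= 0 || te_ms >= tr_ms) stop("te_ms must lie in (0, tr_ms)")
  if (window_ms <= 0) stop("window_ms must be positive")
  if (flip_min_deg > flip_max_deg) stop("flip_min_deg must be <= flip_max_deg")
  if (length(t2prep_times_ms) != prep_cycle_length - 2L)
    stop("need one T2-prep time per T2-prep heartbeat of the cycle (cycle length - 2)")
  structure(list(
    n_heartbeats = as.integer(n_heartbeats), window_ms = window_ms,
    tr_ms = tr_ms, te_ms = te_ms, flip_min_deg = flip_min_deg,
    flip_max_deg = flip_max_deg, inversion_delay_ms = inversion_delay_ms,
    t2prep_times_ms = as.numeric(t2prep_times_ms),
    prep_cycle_length = as.integer(prep_cycle_length)
  ), class = "cmrf_sequence_params")
}

#' Cardiac rhythm (RR interval) timing
#'
#' RR interval i is the elapsed time in ms between the end of the acquisition
#' window in heartbeat i and the beginning of the acquisition window in
#' heartbeat i + 1, as recorded by the ECG.
#'
#' @param rr_intervals_ms Numeric vector of gaps (ms), length
#'   `n_heartbeats - 1`; all entries positive.
#' @return An object of class `cmrf_cardiac_rhythm`.
#' @export
cardiac_rhythm <- function(rr_intervals_ms) {
  rr <- as.numeric(rr_intervals_ms)
  if (length(rr) && any(!is.finite(rr) | rr <= 0))
    stop("all RR intervals must be positive and finite")
  structure(list(rr_intervals_ms = rr), class = "cmrf_cardiac_rhythm")
}

#' Constant heart-rate rhythm
#'
#' Convenience constructor for a regular rhythm: the beat-to-beat period is
#' `60000 / bpm` ms and the recorded RR gap is that period minus the
#' acquisition window.
#'
#' @param params A [sequence_params()] object.
#' @param bpm Heart rate in beats per minute (default 60, as in the phantom
#'   experiment).
#' @return A [cardiac_rhythm()] of length `n_heartbeats - 1`.
#' @export
constant_rhythm <- function(params, bpm = 60) {
  gap <- 60000 / bpm - params$window_ms
  if (gap <= 0) stop("acquisition window does not fit within the cardiac period")
  cardiac_rhythm(rep(gap, max(params$n_heartbeats - 1L, 0L)))
}

#' Number of images (TRs) acquired per heartbeat
#'
#' The acquisition window is filled with as many TRs as fit, rounding the
#' ratio window/TR to the nearest integer with ties rounding up. This is the
#' counting rule consistent with all published scan variants (47, 37, 28,
#' 19 and 9 images per heartbeat).
#'
#' @param window_ms Acquisition window (ms), positive.
#' @param tr_ms Repetition time (ms), positive.
#' @return Integer count of TRs per heartbeat.
#' @export
images_per_heartbeat <- function(window_ms, tr_ms) {
  if (window_ms <= 0 || tr_ms <= 0)
    stop("window_ms and tr_ms must be positive")
  as.integer(floor(window_ms / tr_ms + 0.5))
}

#' Variable flip-angle series for one heartbeat
#'
#' The base design is a sinusoidal ramp over the full 254 ms window
#' (47 entries) rising from `flip_min_deg` to `flip_max_deg` and back.
#' Shortened acquisition windows truncate this pattern, keeping its first
#' entries, so shortened scans share the leading flip angles of the full
#' scan. A user-supplied pattern can replace the default via
#' [build_schedule()].
#'
#' @param n_per_heartbeat Number of TRs in the window, >= 1.
#' @param params A [sequence_params()] object (flip range).
#' @return Numeric vector of flip angles in degrees, length `n_per_heartbeat`.
#' @export
flip_angle_series <- function(n_per_heartbeat, params = sequence_params()) {
  n <- as.integer(n_per_heartbeat)
  if (is.na(n) || n < 1) stop("n_per_heartbeat must be >= 1")
  n_base <- max(n, images_per_heartbeat(254, params$tr_ms))
  ramp <- sin(pi * seq(0, 1, length.out = n_base))
  base <- params$flip_min_deg + (params$flip_max_deg - params$flip_min_deg) * ramp
  base[seq_len(n)]
}

prep_kind_for_heartbeat <- function(h, params) {
  pos <- ((h - 1L) %% params$prep_cycle_length) + 1L
  if (pos == 1L) {
    list(kind = "inversion", duration_ms = params$inversion_delay_ms)
  } else if (pos == 2L) {
    list(kind = "none", duration_ms = 0)
  } else {
    list(kind = "t2prep", duration_ms = params$t2prep_times_ms[pos - 2L])
  }
}

#' Build the per-TR cardiac MRF schedule
#'
#' Expands sequence parameters and a cardiac rhythm into a deterministic
#' per-TR event list: total TR count, flip angle per TR, and the
#' magnetization-preparation event preceding each heartbeat's window.
#' Preparation pulses are applied immediately before the acquisition window;
#' their duration is taken out of the preceding RR relaxation gap.
#'
#' @param params A [sequence_params()] object.
#' @param rhythm A [cardiac_rhythm()] with `n_heartbeats - 1` entries;
#'   defaults to a constant 60 bpm rhythm.
#' @param flip_pattern Optional numeric vector overriding the default flip
#'   waveform; it is truncated (or must be long enough) to the per-heartbeat
#'   TR count.
#' @return An object of class `cmrf_schedule` with fields
#'   `n_per_heartbeat`, `total_trs`, `flip_deg`, `prep_events` (data.frame
#'   with columns heartbeat, kind, duration_ms), `tr_ms`, `te_ms`, `rhythm`
#'   and `params`.
#' @export
build_schedule <- function(params = sequence_params(), rhythm = NULL,
                           flip_pattern = NULL) {
  if (is.null(rhythm)) rhythm <- constant_rhythm(params)
  if (!inherits(rhythm, "cmrf_cardiac_rhythm")) rhythm <- cardiac_rhythm(rhythm)
  if (length(rhythm$rr_intervals_ms) != params$n_heartbeats - 1L)
    stop("rhythm must have n_heartbeats - 1 RR intervals")
  n_per <- images_per_heartbeat(params$window_ms, params$tr_ms)
  if (is.null(flip_pattern)) {
    flips_hb <- flip_angle_series(n_per, params)
  } else {
    if (length(flip_pattern) < n_per)
      stop("flip_pattern shorter than the per-heartbeat TR count")
    flips_hb <- as.numeric(flip_pattern[seq_len(n_per)])
  }
  preps <- lapply(seq_len(params$n_heartbeats), prep_kind_for_heartbeat,
                  params = params)
  prep_events <- data.frame(
    heartbeat = seq_len(params$n_heartbeats),
    kind = vapply(preps, `[[`, character(1), "kind"),
    duration_ms = vapply(preps, `[[`, numeric(1), "duration_ms"),
    stringsAsFactors = FALSE
  )
  structure(list(
    n_per_heartbeat = n_per,
    total_trs = params$n_heartbeats * n_per,
    flip_deg = rep(flips_hb, params$n_heartbeats),
    prep_events = prep_events,
    tr_ms = params$tr_ms, te_ms = params$te_ms,
    rhythm = rhythm, params = params
  ), class = "cmrf_schedule")
}

#' @export
print.cmrf_schedule <- function(x, ...) {
  cat(sprintf("Cardiac MRF schedule: %d heartbeats x %d TRs = %d images\n",
              x$params$n_heartbeats, x$n_per_heartbeat, x$total_trs))
  cat(sprintf("  TR/TE %.1f/%.1f ms, flips %.1f-%.1f deg, window %.0f ms\n",
              x$tr_ms, x$te_ms, min(x$flip_deg), max(x$flip_deg),
              x$params$window_ms))
  tab <- table(x$prep_events$kind)
  cat("  prep events:",
      paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

schedule_as_list <- function(schedule) {
  list(
    params = unclass(schedule$params),
    rhythm = schedule$rhythm$rr_intervals_ms,
    n_per_heartbeat = schedule$n_per_heartbeat,
    total_trs = schedule$total_trs,
    flip_deg = schedule$flip_deg,
    prep_events = list(
      heartbeat = schedule$prep_events$heartbeat,
      kind = schedule$prep_events$kind,
      duration_ms = schedule$prep_events$duration_ms
    )
  )
}

#' Write / read a schedule to YAML or JSON
#'
#' @param schedule A `cmrf_schedule`.
#' @param path Output file; the extension (`.yaml`/`.yml` or `.json`)
#'   selects the format.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns the reconstructed `cmrf_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  x <- schedule_as_list(schedule)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15L)
  }
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  p <- x$params
  params <- sequence_params(
    n_heartbeats = p$n_heartbeats, window_ms = p$window_ms, tr_ms = p$tr_ms,
    te_ms = p$te_ms, flip_min_deg = p$flip_min_deg,
    flip_max_deg = p$flip_max_deg,
    inversion_delay_ms = p$inversion_delay_ms,
    t2prep_times_ms = unlist(p$t2prep_times_ms),
    prep_cycle_length = p$prep_cycle_length
  )
  build_schedule(params, cardiac_rhythm(unlist(x$rhythm)),
                 flip_pattern = unlist(x$flip_deg)[seq_len(x$n_per_heartbeat)])
}
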