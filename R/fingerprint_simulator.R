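prep_kind_codes <- c(none = 0L, inversion = 1L, t2prep = 2L)

schedule_epg_args <- function(schedule) {
  list(
    flip_rad = schedule$flip_deg * pi / 180,
    n_per = schedule$n_per_heartbeat,
    tr_ms = schedule$tr_ms, te_ms = schedule$te_ms,
    prep_kind = unname(prep_kind_codes[schedule$prep_events$kind]),
    prep_dur = schedule$prep_events$duration_ms,
    rr_ms = schedule$rhythm$rr_intervals_ms
  )
}

#' Simulate a cardiac MRF fingerprint
#'
#' Runs an extended-phase-graph (EPG) simulation of the FISP sequence
#' described by a schedule: per-TR excitation at the scheduled flip angle,
#' signal sampled at the echo time, relaxation over TR, unbalanced gradient
#' spoiling, ideal inversion and T2-preparation modules before each
#' heartbeat's window, and free relaxation over the RR gaps.
#'
#' @param t1_ms,t2_ms Relaxation times in ms, positive.
#' @param schedule A [build_schedule()] object.
#' @param n_states Number of EPG dephasing orders retained (default 20).
#' @return Complex vector of length `schedule$total_trs`.
#' @export
simulate_fingerprint <- function(t1_ms, t2_ms, schedule, n_states = 20L) {
  if (any(t1_ms <= 0) || any(t2_ms <= 0))
    stop("relaxation times must be positive")
  a <- schedule_epg_args(schedule)
  D <- epg_simulate_cpp(t1_ms, t2_ms, a$flip_rad, a$n_per, a$tr_ms, a$te_ms,
                        a$prep_kind, a$prep_dur, a$rr_ms, as.integer(n_states))
  if (length(t1_ms) == 1L) drop(D[1L, ]) else D
}

#' Default dictionary grids
#'
#' T1 is sampled at 10 ms steps from 50-2000 ms and 20 ms steps from
#' 2000-3000 ms; T2 at 2 ms steps from 5-100 ms, 5 ms from 100-200 ms and
#' 20 ms from 200-1000 ms. With the physical T2 < T1 filter this yields a
#' dictionary of roughly 23,000 fingerprints.
#'
#' @return Numeric vector of grid values in ms.
#' @export
default_t1_grid <- function() c(seq(50, 2000, by = 10), seq(2020, 3000, by = 20))

#' @rdname default_t1_grid
#' @export
default_t2_grid <- function() c(seq(5, 99, by = 2), seq(100, 200, by = 5),
                                seq(220, 1000, by = 20))

#' Build a cardiac MRF dictionary
#'
#' Simulates one fingerprint per retained (T1, T2) grid pair; pairs with
#' T2 >= T1 are excluded as unphysical.
#'
#' @param schedule A [build_schedule()] object.
#' @param t1_grid,t2_grid Relaxation-time grids in ms (defaults span
#'   T1 50-3000 ms and T2 5-1000 ms).
#' @param n_states EPG dephasing orders (default 20).
#' @return An object of class `cmrf_dictionary` with fields `entries`
#'   (data.frame of t1_ms, t2_ms), `D` (complex p x t matrix) and
#'   `schedule`.
#' @export
build_dictionary <- function(schedule, t1_grid = default_t1_grid(),
                             t2_grid = default_t2_grid(), n_states = 20L) {
  if (!length(t1_grid) || !length(t2_grid)) stop("grids must be non-empty")
  grid <- expand.grid(t1_ms = t1_grid, t2_ms = t2_grid)
  grid <- grid[grid$t2_ms < grid$t1_ms, , drop = FALSE]
  rownames(grid) <- NULL
  a <- schedule_epg_args(schedule)
  D <- epg_simulate_cpp(grid$t1_ms, grid$t2_ms, a$flip_rad, a$n_per,
                        a$tr_ms, a$te_ms, a$prep_kind, a$prep_dur, a$rr_ms,
                        as.integer(n_states))
  structure(list(entries = grid, D = D, schedule = schedule),
            class = "cmrf_dictionary")
}

#' @export
print.cmrf_dictionary <- function(x, ...) {
  cat(sprintf("Cardiac MRF dictionary: %d fingerprints x %d time points\n",
              nrow(x$D), ncol(x$D)))
  cat(sprintf("  T1 %.0f-%.0f ms, T2 %.0f-%.0f ms (T2 < T1)\n",
              min(x$entries$t1_ms), max(x$entries$t1_ms),
              min(x$entries$t2_ms), max(x$entries$t2_ms)))
  invisible(x)
}

#' Low-rank temporal subspace of a dictionary
#'
#' Computes the singular value decomposition of the complex dictionary and
#' keeps the first k right singular vectors as temporal basis functions.
#' The retained energy fraction is the ratio of the sum of the first k
#' squared singular values to the total. For reproducibility each basis
#' column is phase-rotated so its largest-magnitude entry is real positive.
#'
#' @param dictionary A [build_dictionary()] object.
#' @param k Subspace rank (default 5).
#' @return An object of class `cmrf_subspace` with fields `V_k`
#'   (complex t x k, orthonormal columns), `k`, `energy_fraction` and
#'   `singular_values`.
#' @export
compute_subspace <- function(dictionary, k = 5L) {
  D <- dictionary$D
  t <- ncol(D)
  if (k < 1 || k > t) stop("k must lie in [1, number of time points]")
  sv <- svd(D, nu = 0, nv = t)
  V_k <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(Mod(V_k[, j]))
    ph <- V_k[i_max, j] / Mod(V_k[i_max, j])
    V_k[, j] <- V_k[, j] / ph
  }
  structure(list(
    V_k = V_k, k = as.integer(k),
    energy_fraction = sum(sv$d[seq_len(k)]^2) / sum(sv$d^2),
    singular_values = sv$d
  ), class = "cmrf_subspace")
}

#' @export
print.cmrf_subspace <- function(x, ...) {
  cat(sprintf("MRF temporal subspace: rank %d over %d time points, %.4f%% energy\n",
              x$k, nrow(x$V_k), 100 * x$energy_fraction))
  invisible(x)
}

#' Compress a dictionary into a temporal subspace
#'
#' @param dictionary A [build_dictionary()] object.
#' @param subspace A [compute_subspace()] object derived from a dictionary
#'   with the same number of time points.
#' @return Complex p x k matrix of subspace coefficients (D times V_k).
#' @export
compress_dictionary <- function(dictionary, subspace) {
  if (ncol(dictionary$D) != nrow(subspace$V_k))
    stop("dictionary and subspace have incompatible time dimensions")
  dictionary$D %*% subspace$V_k
}
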