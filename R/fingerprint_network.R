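#' Pre-train the fingerprint generator network (FGN)
#'
#' The FGN is a fully-connected surrogate for the extended-phase-graph
#' simulator: it maps a (T1, T2) pair and the scan's RR interval vector to
#' the fingerprint of the schedule, encoded as interleaved real and
#' imaginary parts of length 2t. It is trained once per schedule on
#' simulated fingerprints drawn over the dictionary parameter range and a
#' distribution of cardiac rhythms; targets are unit-l2-normalized so the
#' complex M0 scale is absorbed downstream. Inputs are normalized by
#' fixed constants (3000 ms for T1 and T2, 2000 ms for RR gaps). Two
#' hidden layers of 300 units (leaky ReLU) and a linear output are used.
#'
#' @param schedule A [build_schedule()] object (fixes t).
#' @param n_train Number of training samples (validation split included).
#' @param epochs,batch,lr Adam training configuration.
#' @param seed Integer seed controlling sampling and initialization.
#' @param t1_range,t2_range Sampling ranges in ms (T2 < T1 enforced).
#' @param rr_range RR-gap sampling range in ms (independent per gap).
#' @param val_frac Validation fraction.
#' @param patience Early-stopping patience in epochs.
#' @param n_states EPG state count for the simulated targets.
#' @param tol Median relative l2 validation error above which training is
#'   declared non-convergent.
#' @return An object of class `cmrf_fgn`: `weights`, `t`, `n_rr`,
#'   normalization constants, sampling ranges, and holdout error summary.
#' @export
pretrain_fgn <- function(schedule, n_train = 30000L, epochs = 60L,
                         batch = 64L, lr = 1e-3, seed = 1L,
                         t1_range = c(50, 3000), t2_range = c(5, 1000),
                         rr_range = c(500, 1500), val_frac = 0.1,
                         patience = 10L, n_states = 20L, tol = 0.05) {
  n_rr <- length(schedule$rhythm$rr_intervals_ms)
  a <- schedule_epg_args(schedule)
  sim <- with_seed(derive_seed(seed, "fgn-train"), {
    t1 <- runif(n_train, t1_range[1], t1_range[2])
    t2 <- runif(n_train, t2_range[1], t2_range[2])
    bad <- t2 >= t1
    while (any(bad)) {
      t1[bad] <- runif(sum(bad), t1_range[1], t1_range[2])
      t2[bad] <- runif(sum(bad), t2_range[1], t2_range[2])
      bad <- t2 >= t1
    }
    rr <- matrix(runif(n_train * n_rr, rr_range[1], rr_range[2]),
                 n_train, n_rr)
    list(t1 = t1, t2 = t2, rr = rr)
  })
  D <- epg_simulate_rr_cpp(sim$t1, sim$t2, a$flip_rad, a$n_per, a$tr_ms,
                           a$te_ms, a$prep_kind, a$prep_dur, sim$rr,
                           as.integer(n_states))
  nrm <- sqrt(rowSums(Mod(D)^2))
  nrm[nrm == 0] <- 1
  D <- D / nrm
  t_len <- ncol(D)
  Y <- matrix(0, n_train, 2L * t_len)
  Y[, seq(1, 2 * t_len, by = 2)] <- Re(D)
  Y[, seq(2, 2 * t_len, by = 2)] <- Im(D)
  X <- cbind(sim$t1 / 3000, sim$t2 / 3000, sim$rr / 2000)
  fit <- mlp_train_cpp(X, Y, c(300L, 300L), as.integer(epochs),
                       as.integer(batch), lr, derive_seed(seed, "fgn-fit"),
                       val_frac, as.integer(patience))
  model <- structure(list(
    weights = fit$weights, t = t_len, n_rr = n_rr,
    t1_norm = 3000, t2_norm = 3000, rr_norm = 2000,
    t1_range = t1_range, t2_range = t2_range, rr_range = rr_range,
    train_loss = as.vector(fit$train_loss),
    val_loss = as.vector(fit$val_loss),
    schedule_total_trs = schedule$total_trs
  ), class = "cmrf_fgn")
  hold <- fgn_holdout_error(model, schedule, n = 1500L,
                            seed = derive_seed(seed, "fgn-holdout"),
                            n_states = n_states)
  model$holdout_median_rel_err <- stats::median(hold)
  if (model$holdout_median_rel_err > tol)
    stop(sprintf(
      "FGN pre-training did not converge: median holdout error %.3f > %.3f",
      model$holdout_median_rel_err, tol))
  model
}

fgn_holdout_error <- function(model, schedule, n = 1500L, seed = 1L,
                              n_states = 20L) {
  a <- schedule_epg_args(schedule)
  s <- with_seed(seed, {
    t1 <- runif(n, model$t1_range[1], model$t1_range[2])
    t2 <- runif(n, model$t2_range[1], model$t2_range[2])
    keep <- t2 < t1
    rr <- matrix(runif(n * model$n_rr, model$rr_range[1], model$rr_range[2]),
                 n, model$n_rr)
    list(t1 = t1[keep], t2 = t2[keep], rr = rr[keep, , drop = FALSE])
  })
  D <- epg_simulate_rr_cpp(s$t1, s$t2, a$flip_rad, a$n_per, a$tr_ms,
                           a$te_ms, a$prep_kind, a$prep_dur, s$rr,
                           as.integer(n_states))
  D <- D / sqrt(rowSums(Mod(D)^2))
  Fhat <- fgn_forward(model, s$t1, s$t2, s$rr)
  sqrt(rowSums(Mod(Fhat - D)^2)) / sqrt(rowSums(Mod(D)^2))
}

#' @export
print.cmrf_fgn <- function(x, ...) {
  cat(sprintf(
    "Fingerprint generator network: (T1, T2, %d RR gaps) -> 2 x %d, median holdout error %.2f%%\n",
    x$n_rr, x$t, 100 * x$holdout_median_rel_err))
  invisible(x)
}

#' Evaluate the fingerprint generator network
#'
#' Batched forward pass: m (T1, T2) pairs with either one shared rhythm or
#' one rhythm per row. The interleaved real/imaginary output is
#' de-interleaved into complex fingerprints of length t.
#'
#' @param model A [pretrain_fgn()] object.
#' @param t1_ms,t2_ms Numeric vectors of relaxation times (recycled to a
#'   common length).
#' @param rhythm A [cardiac_rhythm()], numeric RR vector, or matrix with
#'   one RR row per (T1, T2) pair.
#' @return Complex matrix m x t (a plain vector for m = 1).
#' @export
fgn_forward <- function(model, t1_ms, t2_ms, rhythm) {
  m <- max(length(t1_ms), length(t2_ms))
  t1_ms <- rep_len(t1_ms, m)
  t2_ms <- rep_len(t2_ms, m)
  if (inherits(rhythm, "cmrf_cardiac_rhythm")) rhythm <- rhythm$rr_intervals_ms
  rr <- if (is.matrix(rhythm)) rhythm else
    matrix(rhythm, m, length(rhythm), byrow = TRUE)
  if (ncol(rr) != model$n_rr || nrow(rr) != m)
    stop("rhythm does not match the model's heartbeat structure")
  if (any(t1_ms < model$t1_range[1] | t1_ms > model$t1_range[2]) ||
      any(t2_ms < model$t2_range[1] | t2_ms > model$t2_range[2]))
    warning("T1/T2 inputs outside the FGN training range")
  X <- cbind(t1_ms / model$t1_norm, t2_ms / model$t2_norm,
             rr / model$rr_norm)
  O <- mlp_forward_cpp(model$weights, X)
  out <- matrix(complex(real = O[, seq(1, 2 * model$t, by = 2)],
                        imaginary = O[, seq(2, 2 * model$t, by = 2)]),
                m, model$t)
  if (m == 1L) drop(out) else out
}

#' Regenerate a dictionary through the FGN
#'
#' Convenience wrapper producing an FGN-generated dictionary on a (T1, T2)
#' grid for a fixed rhythm, in the same container as [build_dictionary()]
#' (useful for deriving the temporal subspace from the network instead of
#' the simulator).
#'
#' @param model A [pretrain_fgn()] object.
#' @param rhythm RR interval vector or [cardiac_rhythm()].
#' @param t1_grid,t2_grid Grids in ms; pairs with T2 >= T1 are excluded.
#' @return A `cmrf_dictionary` (with `schedule = NULL`).
#' @export
fgn_dictionary <- function(model, rhythm, t1_grid = default_t1_grid(),
                           t2_grid = default_t2_grid()) {
  grid <- expand.grid(t1_ms = t1_grid, t2_ms = t2_grid)
  grid <- grid[grid$t2_ms < grid$t1_ms, , drop = FALSE]
  rownames(grid) <- NULL
  D <- fgn_forward(model, grid$t1_ms, grid$t2_ms, rhythm)
  structure(list(entries = grid, D = D, schedule = NULL),
            class = "cmrf_dictionary")
}
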