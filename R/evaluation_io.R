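#' Normalized root mean square error (percent)
#'
#' `100 * ||(estimate - truth)[mask]||_2 / ||truth[mask]||_2`, the map
#' error metric used throughout, computed over non-background voxels.
#'
#' @param estimate,truth Numeric maps of identical size.
#' @param mask Logical map selecting the voxels entering the metric.
#' @return List with `value_pct` and the `mask` used.
#' @export
nrmse <- function(estimate, truth, mask) {
  if (!all(dim(estimate) == dim(truth)))
    stop("estimate and truth must have identical dimensions")
  if (!any(mask)) stop("mask is empty")
  denom <- sqrt(sum(truth[mask]^2))
  if (denom == 0) stop("truth is identically zero on the mask")
  list(value_pct = 100 * sqrt(sum((estimate[mask] - truth[mask])^2)) / denom,
       mask = mask)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `b - a`; the bias is their mean and the 95%
#' limits of agreement are bias +/- 1.96 times their sample standard
#' deviation.
#'
#' @param a,b Paired measurement vectors of equal length >= 2.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need paired vectors of equal length >= 2")
  d <- b - a
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s)
}

#' Inter- and intra-subject variability
#'
#' Intersubject variability is the standard deviation of the per-subject
#' means; intrasubject variability is the mean of the per-subject
#' standard deviations.
#'
#' @param means Per-subject mean values (length >= 2).
#' @param sds Per-subject standard deviations (same length).
#' @return List with `intersubject` and `intrasubject`.
#' @export
variability_stats <- function(means, sds) {
  if (length(means) < 2 || length(means) != length(sds))
    stop("need at least two subjects with matching means and sds")
  list(intersubject = sd(means), intrasubject = mean(sds))
}

#' Run the simulation study
#'
#' Replicates the structure of the simulation experiments: for each
#' sequence variant and k-space noise level, one spiral acquisition of the
#' numerical cardiac phantom is simulated and reconstructed with each
#' requested method (per-TR gridding + dictionary matching, SLLR, and
#' DIP), reporting T1/T2 nRMSE against the phantom ground truth over
#' non-background voxels. All reconstructions of one (variant, noise)
#' cell share the same simulated data; every cell derives an independent
#' seed from the master seed.
#'
#' @param variants List of lists with `n_heartbeats` and `window_ms`.
#' @param noise_levels Noise SD as percent of the DC maximum.
#' @param methods Subset of `c("direct", "sllr", "dip")`.
#' @param matrix Matrix size (phantom and reconstruction).
#' @param n_coils Number of coils.
#' @param seed Master seed.
#' @param dict_t1_step,dict_t2_step Dictionary grid steps (ms) for the
#'   matching-based methods; the subspace always uses this dictionary.
#' @param dip Arguments passed on to [dip_config()] (list).
#' @param fgn_n_train,fgn_epochs FGN pre-training size (per variant).
#' @param spiral_dwell_us Spiral dwell time (sets samples per readout).
#' @param sllr A [sllr_config()].
#' @param out_csv Optional path; the results table is written as CSV.
#' @param verbose Print per-cell progress.
#' @return data.frame with columns variant, n_heartbeats, window_ms,
#'   noise_pct, method, t1_nrmse, t2_nrmse, seconds.
#' @export
run_simulation_study <- function(variants = list(list(n_heartbeats = 5L,
                                                      window_ms = 150)),
                                 noise_levels = 0.1,
                                 methods = c("direct", "sllr", "dip"),
                                 matrix = 64L, n_coils = 8L, seed = 1L,
                                 dict_t1_step = 20, dict_t2_step = 4,
                                 dip = list(), fgn_n_train = 30000L,
                                 fgn_epochs = 25L, spiral_dwell_us = 10,
                                 sllr = sllr_config(), out_csv = NULL,
                                 verbose = interactive()) {
  methods <- match.arg(methods, several.ok = TRUE)
  phantom <- make_cardiac_phantom(matrix, matrix,
                                  seed = derive_seed(seed, "phantom"))
  csm_true <- make_coil_maps(matrix, matrix, n_coils,
                             seed = derive_seed(seed, "coils"))
  traj <- make_spiral(matrix = matrix, n_interleaves = 48L,
                      dwell_us = spiral_dwell_us)
  fg_mask <- phantom$labels > 0
  rows <- list()
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    params <- sequence_params(n_heartbeats = v$n_heartbeats,
                              window_ms = v$window_ms)
    schedule <- build_schedule(params)
    t1g <- seq(50, 2000, by = dict_t1_step)
    t2g <- seq(5, 300, by = dict_t2_step)
    dict <- build_dictionary(schedule, t1g, t2g)
    sub <- compute_subspace(dict, 5L)
    D_k <- compress_dictionary(dict, sub)
    fgn <- if ("dip" %in% methods)
      pretrain_fgn(schedule, n_train = fgn_n_train, epochs = fgn_epochs,
                   seed = derive_seed(seed, paste0("fgn", vi)))
    else NULL
    for (nz in noise_levels) {
      cell_seed <- derive_seed(seed, sprintf("cell-%d-%g", vi, nz))
      acq <- simulate_acquisition(phantom, schedule, csm_true, traj,
                                  noise_pct = nz, seed = cell_seed)
      cal <- self_calibration(acq)
      csm <- cal$csm
      ops <- calibrate_grog(cal$calib)
      cart <- NULL
      for (m in methods) {
        t0 <- Sys.time()
        maps <- switch(
          m,
          direct = direct_match(acq, dict, csm),
          sllr = {
            rec <- sllr_reconstruct(acq, sub, csm, sllr)
            match_compressed(rec$x_k, D_k, dict$entries)
          },
          dip = {
            if (is.null(cart)) cart <- grog_grid(acq, ops, csm)
            cfg <- do.call(dip_config, utils::modifyList(
              list(seed = derive_seed(cell_seed, "dip")), dip))
            dip_reconstruct(cart, sub, fgn, cfg)$maps
          })
        secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
        r1 <- nrmse(maps$t1_map, phantom$t1_map, fg_mask)$value_pct
        r2 <- nrmse(maps$t2_map, phantom$t2_map, fg_mask)$value_pct
        rows[[length(rows) + 1L]] <- data.frame(
          variant = sprintf("%dHB/%gms", v$n_heartbeats, v$window_ms),
          n_heartbeats = v$n_heartbeats, window_ms = v$window_ms,
          noise_pct = nz, method = m, t1_nrmse = r1, t2_nrmse = r2,
          seconds = secs, stringsAsFactors = FALSE)
        if (verbose)
          message(sprintf("%s noise %.2g%% %-6s T1 %.2f%% T2 %.2f%% (%.1fs)",
                          rows[[length(rows)]]$variant, nz, m, r1, r2, secs))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Write parameter maps as NIfTI
#'
#' T1, T2, |M0| and the M0 phase are written as separate single-volume
#' NIfTI files with a common prefix.
#'
#' @param maps A `cmrf_parameter_maps` object.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file names.
#' @export
write_maps_nifti <- function(maps, prefix) {
  files <- c(t1 = paste0(prefix, "_t1.nii.gz"),
             t2 = paste0(prefix, "_t2.nii.gz"),
             m0_mag = paste0(prefix, "_m0_mag.nii.gz"),
             m0_phase = paste0(prefix, "_m0_phase.nii.gz"))
  RNifti::writeNifti(maps$t1_map, files["t1"])
  RNifti::writeNifti(maps$t2_map, files["t2"])
  RNifti::writeNifti(Mod(maps$m0_map), files["m0_mag"])
  RNifti::writeNifti(Arg(maps$m0_map), files["m0_phase"])
  invisible(files)
}
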