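# Independent brute-force oracles used to validate the fast implementations.

# Isochromat-summation simulation of the FISP cardiac MRF sequence: a fan
# of spins uniformly dephased across the voxel, rotated explicitly per TR.
# Same physics model as the EPG engine (ideal preps, relaxation over full
# TR, signal at TE) but a completely different numerical mechanism.
isochromat_fingerprint <- function(t1, t2, schedule, n_iso = 256L) {
  theta <- 2 * pi * (seq_len(n_iso) - 1) / n_iso
  ct <- cos(theta); st <- sin(theta)
  mx <- my <- rep(0, n_iso); mz <- rep(1, n_iso)
  e1 <- function(tau) exp(-tau / t1)
  e2 <- function(tau) exp(-tau / t2)
  sig <- complex(schedule$total_trs)
  j <- 0L
  for (h in seq_len(nrow(schedule$prep_events))) {
    if (h > 1L) {
      gap <- max(schedule$rhythm$rr_intervals_ms[h - 1] -
                   schedule$prep_events$duration_ms[h], 0)
      mx <- mx * e2(gap); my <- my * e2(gap)
      mz <- 1 + (mz - 1) * e1(gap)
    }
    kind <- schedule$prep_events$kind[h]
    dur <- schedule$prep_events$duration_ms[h]
    if (kind == "inversion") {
      mx[] <- 0; my[] <- 0; mz <- -mz
      mz <- 1 + (mz - 1) * e1(dur)
    } else if (kind == "t2prep") {
      mx[] <- 0; my[] <- 0
      mz <- mz * exp(-dur / t2)
    }
    for (i in seq_len(schedule$n_per_heartbeat)) {
      j <- j + 1L
      al <- schedule$flip_deg[j] * pi / 180
      my_new <- my * cos(al) - mz * sin(al)
      mz <- my * sin(al) + mz * cos(al)
      my <- my_new
      sig[j] <- mean(complex(real = mx, imaginary = my)) *
        exp(-schedule$te_ms / t2)
      mx <- mx * e2(schedule$tr_ms); my <- my * e2(schedule$tr_ms)
      mz <- 1 + (mz - 1) * e1(schedule$tr_ms)
      mx_new <- mx * ct - my * st
      my <- mx * st + my * ct
      mx <- mx_new
    }
  }
  sig
}

# Naive double-loop non-uniform DFT (forward), centered convention.
brute_nudft <- function(image, coords) {
  n_y <- nrow(image); n_x <- ncol(image)
  pos_y <- (seq_len(n_y) - 1) - n_y %/% 2
  pos_x <- (seq_len(n_x) - 1) - n_x %/% 2
  out <- complex(nrow(coords))
  for (s in seq_len(nrow(coords))) {
    acc <- 0 + 0i
    for (ix in seq_len(n_x)) {
      for (iy in seq_len(n_y)) {
        acc <- acc + image[iy, ix] *
          exp(-2i * pi * (coords[s, 1] * pos_x[ix] / n_x +
                            coords[s, 2] * pos_y[iy] / n_y))
      }
    }
    out[s] <- acc / sqrt(n_y * n_x)
  }
  out
}

# Explicit loop-nest version of the Cartesian per-frame forward model.
brute_forward_frame <- function(x_k, csm, V_k, P_i, W, i) {
  n_y <- dim(x_k)[1]; n_x <- dim(x_k)[2]
  k <- dim(x_k)[3]; n_coils <- dim(csm$S)[3]
  out <- array(0 + 0i, dim = c(n_y, n_x, n_coils))
  frame <- matrix(0 + 0i, n_y, n_x)
  for (j in seq_len(k)) frame <- frame + x_k[, , j] * Conj(V_k[i, j])
  for (cc in seq_len(n_coils)) {
    ksp <- matrix(0 + 0i, n_y, n_x)
    src <- frame * csm$S[, , cc]
    pos_y <- (seq_len(n_y) - 1) - n_y %/% 2
    pos_x <- (seq_len(n_x) - 1) - n_x %/% 2
    for (kx in seq_len(n_x)) {
      for (ky in seq_len(n_y)) {
        acc <- 0 + 0i
        for (ix in seq_len(n_x)) {
          for (iy in seq_len(n_y)) {
            acc <- acc + src[iy, ix] *
              exp(-2i * pi * (pos_x[kx] * pos_x[ix] / n_x +
                                pos_y[ky] * pos_y[iy] / n_y))
          }
        }
        ksp[ky, kx] <- acc / sqrt(n_y * n_x)
      }
    }
    out[, , cc] <- W * P_i * ksp
  }
  out
}
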