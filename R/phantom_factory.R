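#' Default phantom tissue parameterization
#'
#' Representative 1.5 T relaxation times (ms) and proton-density magnitudes
#' for the numerical short-axis cardiac phantom. Values are design
#' constants and can be edited before passing to [make_cardiac_phantom()].
#'
#' @return data.frame with columns tissue, label, t1_ms, t2_ms, m0.
#' @export
phantom_tissues <- function() {
  data.frame(
    tissue = c("lv_blood", "rv_blood", "myocardium", "liver", "fat", "lung",
               "muscle"),
    label = c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
    t1_ms = c(1550, 1550, 1000, 590, 260, 1200, 900),
    t2_ms = c(240, 240, 45, 46, 60, 80, 50),
    m0 = c(1.0, 1.0, 0.80, 0.90, 1.10, 0.30, 0.85),
    stringsAsFactors = FALSE
  )
}

in_ellipse <- function(X, Y, cx, cy, a, b) {
  ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
}

#' Generate a numerical short-axis cardiac phantom
#'
#' Builds a deterministic ellipse-based thorax with two lungs, a liver,
#' a subcutaneous fat rim, muscle filling, and a heart consisting of an LV
#' blood pool surrounded by a myocardial annulus plus an RV blood pool.
#' Tissue T1/T2/M0 values receive a per-seed uniform jitter of +/- 3%, and
#' M0 carries a smooth low-order phase ramp so complex-M0 estimation is
#' exercised. Background voxels have M0 = 0.
#'
#' @param n_y,n_x Matrix size in voxels, both >= 32.
#' @param seed Integer seed; the phantom is a pure function of
#'   (n_y, n_x, seed, tissues).
#' @param tissues Tissue table as returned by [phantom_tissues()].
#' @param jitter Relative half-width of the per-seed tissue value jitter.
#' @return An object of class `cmrf_phantom` with fields `t1_map`, `t2_map`
#'   (ms, zero in background), `m0_map` (complex), `labels` (integer map,
#'   0 = background) and `tissues` (the jittered table actually used).
#' @export
make_cardiac_phantom <- function(n_y = 64L, n_x = 64L, seed = 1L,
                                 tissues = phantom_tissues(),
                                 jitter = 0.03) {
  if (n_y < 32 || n_x < 32) stop("matrix size must be at least 32 x 32")
  with_seed(derive_seed(seed, "phantom"), {
    tis <- tissues
    tis$t1_ms <- tis$t1_ms * runif(nrow(tis), 1 - jitter, 1 + jitter)
    tis$t2_ms <- tis$t2_ms * runif(nrow(tis), 1 - jitter, 1 + jitter)
    tis$m0 <- tis$m0 * runif(nrow(tis), 1 - jitter, 1 + jitter)
    ph_coef <- c(runif(1, -pi / 4, pi / 4), runif(2, -1.2, 1.2),
                 runif(1, -0.8, 0.8))

    x <- seq(-1, 1, length.out = n_x)
    y <- seq(-1, 1, length.out = n_y)
    X <- matrix(rep(x, each = n_y), n_y, n_x)
    Y <- matrix(rep(y, times = n_x), n_y, n_x)

    lab <- matrix(0L, n_y, n_x)
    body <- in_ellipse(X, Y, 0, 0, 0.92, 0.72)
    inner <- in_ellipse(X, Y, 0, 0, 0.84, 0.64)
    lab[body] <- tis$label[tis$tissue == "fat"]
    lab[inner] <- tis$label[tis$tissue == "muscle"]
    put <- function(lab, mask, tissue)
      `[<-`(lab, mask & inner, tis$label[tis$tissue == tissue])
    lab <- put(lab, in_ellipse(X, Y, -0.45, 0.02, 0.26, 0.40), "lung")
    lab <- put(lab, in_ellipse(X, Y, 0.47, 0.06, 0.22, 0.36), "lung")
    lab <- put(lab, in_ellipse(X, Y, 0.38, -0.42, 0.38, 0.20), "liver")
    r_lv <- 0.15
    heart_c <- c(-0.05, 0.12)
    lab <- put(lab, in_ellipse(X, Y, heart_c[1] - 0.30, heart_c[2] + 0.06,
                               0.16, 0.13), "rv_blood")
    lab <- put(lab, in_ellipse(X, Y, heart_c[1], heart_c[2],
                               r_lv + 0.10, r_lv + 0.10), "myocardium")
    lab <- put(lab, in_ellipse(X, Y, heart_c[1], heart_c[2], r_lv, r_lv),
               "lv_blood")

    t1 <- matrix(0, n_y, n_x)
    t2 <- matrix(0, n_y, n_x)
    m0_mag <- matrix(0, n_y, n_x)
    for (i in seq_len(nrow(tis))) {
      m <- lab == tis$label[i]
      t1[m] <- tis$t1_ms[i]
      t2[m] <- tis$t2_ms[i]
      m0_mag[m] <- tis$m0[i]
    }
    phase <- ph_coef[1] + ph_coef[2] * X + ph_coef[3] * Y + ph_coef[4] * X * Y
    m0 <- m0_mag * exp(1i * phase)
    m0[lab == 0L] <- 0 + 0i

    structure(list(t1_map = t1, t2_map = t2, m0_map = m0, labels = lab,
                   tissues = tis, n_y = as.integer(n_y),
                   n_x = as.integer(n_x), seed = as.integer(seed)),
              class = "cmrf_phantom")
  })
}

#' @export
print.cmrf_phantom <- function(x, ...) {
  cat(sprintf("Cardiac phantom %d x %d, %.0f%% tissue voxels, seed %d\n",
              x$n_y, x$n_x, 100 * mean(x$labels > 0), x$seed))
  invisible(x)
}

#' Generate smooth synthetic coil sensitivity maps
#'
#' Coils are placed around the field-of-view perimeter with Gaussian-lobe
#' magnitude profiles and smooth low-order phase. The root sum of squares
#' over coils is positive at every voxel. A single coil yields a flat unit
#' map.
#'
#' @param n_y,n_x Matrix size.
#' @param n_coils Number of receive channels (default 8).
#' @param seed Integer seed for the small placement/phase jitter.
#' @return An object of class `cmrf_coil_maps` holding `S`, a complex
#'   array of dimension (n_y, n_x, n_coils).
#' @export
make_coil_maps <- function(n_y = 64L, n_x = 64L, n_coils = 8L, seed = 1L) {
  if (n_coils < 1) stop("n_coils must be >= 1")
  S <- array(0 + 0i, dim = c(n_y, n_x, n_coils))
  if (n_coils == 1L) {
    S[, , 1] <- 1 + 0i
  } else {
    with_seed(derive_seed(seed, "coils"), {
      x <- seq(-1, 1, length.out = n_x)
      y <- seq(-1, 1, length.out = n_y)
      X <- matrix(rep(x, each = n_y), n_y, n_x)
      Y <- matrix(rep(y, times = n_x), n_y, n_x)
      for (cc in seq_len(n_coils)) {
        th <- 2 * pi * (cc - 1) / n_coils + runif(1, -0.15, 0.15)
        cx <- 1.35 * cos(th)
        cy <- 1.35 * sin(th)
        d2 <- (X - cx)^2 + (Y - cy)^2
        mag <- exp(-d2 / (2 * 0.85^2))
        phase <- runif(1, -pi, pi) + runif(1, -0.6, 0.6) * X +
          runif(1, -0.6, 0.6) * Y
        S[, , cc] <- mag * exp(1i * phase)
      }
    })
  }
  structure(list(S = S, n_coils = as.integer(n_coils)),
            class = "cmrf_coil_maps")
}

#' @export
print.cmrf_coil_maps <- function(x, ...) {
  cat(sprintf("Coil maps: %d channels, %d x %d\n", x$n_coils,
              dim(x$S)[1], dim(x$S)[2]))
  invisible(x)
}
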