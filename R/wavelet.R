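# Orthonormal Daubechies-4 discrete wavelet transform, periodic boundary,
# applied separably in 2D. Filters are real and the transform is
# orthogonal, so the inverse is the transpose and Parseval holds; this is
# the sparsifying transform of the SLLR baseline.

db4_lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
db4_hi <- rev(db4_lo) * c(1, -1, 1, -1)

dwt_step_cols <- function(m) {
  n <- nrow(m)
  idx <- outer(seq(0, n - 2, by = 2), 0:3, `+`) %% n + 1
  a <- db4_lo[1] * m[idx[, 1], , drop = FALSE]
  d <- db4_hi[1] * m[idx[, 1], , drop = FALSE]
  for (j in 2:4) {
    a <- a + db4_lo[j] * m[idx[, j], , drop = FALSE]
    d <- d + db4_hi[j] * m[idx[, j], , drop = FALSE]
  }
  rbind(a, d)
}

idwt_step_cols <- function(m) {
  n2 <- nrow(m); n <- n2 %/% 2
  a <- m[seq_len(n), , drop = FALSE]
  d <- m[n + seq_len(n), , drop = FALSE]
  out <- matrix(0 + 0i, n2, ncol(m))
  idx <- outer(seq(0, n2 - 2, by = 2), 0:3, `+`) %% n2 + 1
  for (j in 1:4) {
    rows <- idx[, j]
    contrib <- db4_lo[j] * a + db4_hi[j] * d
    out[rows, ] <- out[rows, ] + contrib
  }
  out
}

#' 2D Daubechies-4 wavelet analysis / synthesis
#'
#' Orthonormal periodic transform with `levels` dyadic decompositions of
#' the approximation band. `dwt2` and `idwt2` are exact inverses and
#' preserve the l2 norm.
#'
#' @param x Complex (or numeric) square matrix with side divisible by
#'   `2^levels`.
#' @param levels Number of decomposition levels (default 3).
#' @return Matrix of the same size holding the coefficient layout.
#' @keywords internal
dwt2 <- function(x, levels = 3L) {
  out <- x + 0i
  n <- nrow(x)
  for (l in seq_len(levels)) {
    sub <- out[seq_len(n), seq_len(n), drop = FALSE]
    sub <- dwt_step_cols(sub)
    sub <- t(dwt_step_cols(t(sub)))
    out[seq_len(n), seq_len(n)] <- sub
    n <- n %/% 2
  }
  out
}

#' @rdname dwt2
#' @keywords internal
idwt2 <- function(x, levels = 3L) {
  out <- x + 0i
  n <- nrow(x) %/% 2^(levels - 1)
  for (l in seq_len(levels)) {
    sub <- out[seq_len(n), seq_len(n), drop = FALSE]
    sub <- t(idwt_step_cols(t(sub)))
    sub <- idwt_step_cols(sub)
    out[seq_len(n), seq_len(n)] <- sub
    n <- n * 2
  }
  out
}
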