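# Evaluate expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive an independent 31-bit child seed from a master seed and a label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label, ":", seed)) *
             (31 ^ (seq_along(utf8ToInt(paste0(label, ":", seed))) %% 7)))
  as.integer((seed * 2654435761 + h) %% .Machine$integer.max)
}

fnorm <- function(x) sqrt(sum(Mod(x)^2))

# centered orthonormal 2D FFT: DC at index (n/2 + 1, n/2 + 1)
ft2c <- function(img) {
  n <- sqrt(length(img))
  fftshift2(stats::fft(ifftshift2(img))) / sqrt(length(img))
}

ift2c <- function(ksp) {
  fftshift2(stats::fft(ifftshift2(ksp), inverse = TRUE)) / sqrt(length(ksp))
}

fftshift2 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  m[c((ny %/% 2 + 1):ny, 1:(ny %/% 2)), c((nx %/% 2 + 1):nx, 1:(nx %/% 2))]
}

ifftshift2 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  m[c((ny - ny %/% 2 + 1):ny, 1:(ny - ny %/% 2)),
    c((nx - nx %/% 2 + 1):nx, 1:(nx - nx %/% 2))]
}
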