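#' Centered 2D Fourier transforms and circular shifts
#'
#' k-space conventions used throughout the package: the DC sample sits at
#' 0-based index `floor(N/2)` along each axis (R index `floor(N/2) + 1`),
#' the phase-encode (PE) direction is the row (y) axis, and both transform
#' directions carry orthonormal `1/sqrt(N)` scaling so that Parseval's
#' identity holds exactly.
#'
#' @param img complex (or numeric) matrix, image domain.
#' @return `ft2()` returns centered k-space; `ift2()` its exact inverse.
#' @examples
#' img <- matrix(rnorm(64), 8, 8)
#' max(abs(ift2(ft2(img)) - img)) < 1e-12
#' @export
ft2 <- function(img) {
  fftshift2(stats::fft(ifftshift2(img))) / sqrt(length(img))
}

#' @rdname ft2
#' @param ksp complex matrix, centered k-space.
#' @export
ift2 <- function(ksp) {
  fftshift2(stats::fft(ifftshift2(ksp), inverse = TRUE)) / sqrt(length(ksp))
}

#' Circularly shift a vector or the rows of a matrix
#'
#' `circshift(x, s)[i] == x[i - s]` (indices modulo length): positive `s`
#' moves content toward higher indices.
#'
#' @param x vector.
#' @param s integer shift (may be negative or exceed the length).
#' @export
circshift <- function(x, s) {
  n <- length(x)
  x[((seq_len(n) - 1L - s) %% n) + 1L]
}

#' @rdname circshift
#' @param m matrix; rows (the PE axis) are shifted.
#' @export
circshift_rows <- function(m, s) {
  n <- nrow(m)
  m[((seq_len(n) - 1L - s) %% n) + 1L, , drop = FALSE]
}

#' @rdname ft2
#' @export
fftshift2 <- function(img) {
  img <- circshift_rows(img, floor(nrow(img) / 2))
  t(circshift_rows(t(img), floor(ncol(img) / 2)))
}

#' @rdname ft2
#' @export
ifftshift2 <- function(img) {
  img <- circshift_rows(img, -floor(nrow(img) / 2))
  t(circshift_rows(t(img), -floor(ncol(img) / 2)))
}

# 1D centered orthonormal transforms (used on single readout lines)
ft1 <- function(x) circshift(stats::fft(circshift(x, -floor(length(x) / 2))),
                             floor(length(x) / 2)) / sqrt(length(x))

ift1 <- function(x) circshift(stats::fft(circshift(x, -floor(length(x) / 2)),
                                         inverse = TRUE),
                              floor(length(x) / 2)) / sqrt(length(x))

# Evaluate a function with a private, restorable RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Complex Gaussian noise, sd per complex sample (real and imaginary parts
# each have sd noise_sd / sqrt(2) so that sd(|n|) components match).
complex_noise <- function(n, noise_sd) {
  complex(real = stats::rnorm(n, sd = noise_sd / sqrt(2)),
          imaginary = stats::rnorm(n, sd = noise_sd / sqrt(2)))
}

#' Relative L2 error between two arrays
#'
#' `||x - ref|| / ||ref||` over all elements (complex moduli for complex
#' input); the NRMSE figure used throughout the reconstruction tests.
#' @param x,ref arrays of identical shape.
#' @export
nrmse <- function(x, ref) {
  sqrt(sum(Mod(x - ref)^2)) / sqrt(sum(Mod(ref)^2))
}
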