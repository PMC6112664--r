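#' Simulate smooth complex coil sensitivity maps
#'
#' Generates per-slice 2D complex receive sensitivities for `n_coils`
#' channels: Gaussian magnitude lobes centered on a ring around the FOV
#' (with a slice-dependent azimuthal twist so maps differ between the
#' slices of a multiband group) and a smooth linear phase per coil. Maps
#' are normalized so the sum-of-squares magnitude equals 1 at every pixel,
#' matching a SoS-normalized array-combination convention. A seeded jitter
#' of the lobe centers and widths makes the set reproducible but
#' non-degenerate.
#'
#' @param n_coils integer >= 1.
#' @param grid integer pair `(ny, nx)`.
#' @param n_slices number of slices to generate maps for.
#' @param smoothness Gaussian lobe width in pixels; default `0.7 * max(grid)`.
#'   Larger values give smoother, flatter maps.
#' @param seed integer; the generator is bit-reproducible for a fixed seed.
#' @return object of class `coil_maps`: list with `maps` (complex array
#'   `ny x nx x n_coils x n_slices`), `n_coils`, `grid`, `n_slices`.
#' @export
build_coil_maps <- function(n_coils, grid, n_slices = 1L,
                            smoothness = NULL, seed = 1L) {
  if (n_coils < 1) stop("n_coils must be >= 1")
  ny <- grid[1]; nx <- grid[2]
  if (is.null(smoothness)) smoothness <- 0.7 * max(ny, nx)

  maps <- array(0i, dim = c(ny, nx, n_coils, n_slices))
  if (n_coils == 1) {
    maps[] <- 1 + 0i
    return(structure(list(maps = maps, n_coils = 1L, grid = grid,
                          n_slices = as.integer(n_slices), seed = seed),
                     class = "coil_maps"))
  }

  yy <- matrix(seq_len(ny) - (ny + 1) / 2, ny, nx)
  xx <- matrix(seq_len(nx) - (nx + 1) / 2, ny, nx, byrow = TRUE)
  rring <- 0.6 * max(ny, nx)

  with_seed(seed, {
    jit_a <- stats::runif(n_coils, -0.25, 0.25)        # angle jitter, rad
    jit_r <- stats::runif(n_coils, 0.9, 1.1)           # radius jitter
    jit_w <- stats::runif(n_coils, 0.85, 1.15)         # width jitter
    ph_g <- stats::runif(n_coils, -pi, pi)             # constant phase
    ph_ky <- stats::runif(n_coils, -1.5, 1.5) / max(ny, nx)  # linear phase
    ph_kx <- stats::runif(n_coils, -1.5, 1.5) / max(ny, nx)

    for (z in seq_len(n_slices)) {
      twist <- (z - 1) * pi / (n_slices + 1)
      raw <- array(0i, dim = c(ny, nx, n_coils))
      for (c in seq_len(n_coils)) {
        ang <- 2 * pi * (c - 1) / n_coils + jit_a[c] + twist
        cy <- rring * jit_r[c] * sin(ang)
        cx <- rring * jit_r[c] * cos(ang)
        w <- smoothness * jit_w[c]
        mag <- exp(-(((yy - cy)^2 + (xx - cx)^2)) / (2 * w^2))
        ph <- ph_g[c] + 2 * pi * (ph_ky[c] * yy + ph_kx[c] * xx)
        raw[, , c] <- mag * exp(1i * ph)
      }
      sos <- sqrt(apply(abs(raw)^2, c(1, 2), sum))
      for (c in seq_len(n_coils)) maps[, , c, z] <- raw[, , c] / sos
    }
  })

  structure(list(maps = maps, n_coils = as.integer(n_coils), grid = grid,
                 n_slices = as.integer(n_slices), seed = seed),
            class = "coil_maps")
}

#' @export
print.coil_maps <- function(x, ...) {
  cat(sprintf("<coil_maps> %d coils, %d x %d grid, %d slice(s)\n",
              x$n_coils, x$grid[1], x$grid[2], x$n_slices))
  invisible(x)
}

#' Sum-of-squares coil combination
#'
#' Voxel-wise `sqrt(sum_c |I_c|^2)` over the coil dimension (third axis).
#'
#' @param coil_images complex or numeric array `ny x nx x n_coils`
#'   (a plain matrix is treated as a single coil).
#' @return non-negative magnitude matrix `ny x nx`.
#' @export
sos_combine <- function(coil_images) {
  if (is.matrix(coil_images)) return(Mod(coil_images))
  stopifnot(length(dim(coil_images)) == 3)
  sqrt(apply(Mod(coil_images)^2, c(1, 2), sum))
}
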