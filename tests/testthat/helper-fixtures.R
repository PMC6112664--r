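# Small simulation fixtures shared across test files. All fixtures are
# generated in code; grids are kept small so the whole suite stays fast.

TE3 <- c(9, 21.5, 34)

tiny_phantom <- function(nz = 2L, n = 32L, vessel = TRUE) {
  build_phantom(phantom_spec(
    grid_shape = c(nz, n, n),
    vessel = if (vessel) phantom_spec()$vessel else NULL))
}

uniform_phantom <- function(nz = 1L, n = 32L) {
  build_phantom(phantom_spec(grid_shape = c(nz, n, n),
                             subvols = default_subvols()[0, ],
                             vessel = NULL))
}

# coil_maps object with fully specified maps (for degenerate geometries)
manual_coils <- function(maps) {
  structure(list(maps = maps, n_coils = dim(maps)[3],
                 grid = dim(maps)[1:2], n_slices = dim(maps)[4], seed = 0L),
            class = "coil_maps")
}

# encode a phantom both single-band and SMS with matched parameters
encode_pair <- function(phantom, coils, mb, f, n_segments = 4L,
                        te_list = TE3, tr = 261, fa = 90, noise_sd = 0,
                        ets = 0.15, seed = 1L, n_frames = 1L) {
  nz <- phantom$grid_shape[1]; ny <- phantom$grid_shape[2]
  pl_sms <- plan(ny, n_segments, nz, mb = mb, f = f, te_list = te_list,
                 tr = tr, ets = ets, n_frames = n_frames)
  pl_sb <- plan(ny, n_segments, nz, mb = 1L, f = 1L, te_list = te_list,
                tr = tr, ets = ets)
  par_sms <- acquisition_params(fa = fa, tr = tr, te_list = te_list,
                                n_segments = n_segments,
                                fov_shift_factor = f, mb = mb,
                                noise_sd = noise_sd,
                                ets_us = ets * 1000, seed = seed)
  par_sb <- acquisition_params(fa = fa, tr = tr, te_list = te_list,
                               n_segments = n_segments,
                               fov_shift_factor = 1L, mb = 1L,
                               noise_sd = noise_sd,
                               ets_us = ets * 1000, seed = seed + 1L)
  list(sb = encode_acquisition(phantom, coils, pl_sb, par_sb),
       sms = encode_acquisition(phantom, coils, pl_sms, par_sms),
       plan_sms = pl_sms, plan_sb = pl_sb,
       par_sms = par_sms, par_sb = par_sb)
}

# fraction of unfolded energy leaking out of the only excited slice
leak_fraction <- function(kernel, sb, slice, f, mb) {
  ny <- dim(sb$kspace)[1]; nc <- dim(sb$kspace)[3]
  n0 <- (slice - 1) %/% kernel$n_groups          # in-group index, 0-based
  ph <- caipi_line_phase(n0, f, ny)
  S <- array(0i, c(ny, ny, nc, 1, 1))
  for (cc in seq_len(nc)) {
    S[, , cc, 1, 1] <- sb$kspace[, , cc, 1, slice, 1] * ph
  }
  r <- unfold(S, kernel)
  e <- vapply(seq_len(mb * kernel$n_groups),
              function(z) sum(r$slice_images[, , z, 1]^2), numeric(1))
  sum(e[-slice]) / sum(e)
}
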