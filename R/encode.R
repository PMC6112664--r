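#' Acquisition parameter set
#'
#' Validated container for the parameters of a simulated multi-echo
#' segmented-EPI acquisition. Defaults mirror the emulated dynamic
#' protocol: FA = 90 deg, TR = 261 ms, TE = 9 / 21.5 / 34 ms, 4 segments,
#' multiband factor 4 with a FOV/4 CAIPIRINHA shift, and an echo-time
#' shift of 150 us between adjacent segments.
#'
#' @param fa flip angle, degrees.
#' @param tr repetition time, ms.
#' @param te_list echo times, ms, strictly increasing.
#' @param n_segments number of EPI segments.
#' @param fov_shift_factor CAIPIRINHA shift factor f (shift = FOV/f).
#' @param mb multiband factor (>= 1; 1 = single-band).
#' @param noise_sd per-sample complex-Gaussian noise standard deviation
#'   (k-space units; 0 = noiseless).
#' @param ghost_phase numeric pair `(constant rad, linear rad/sample)`
#'   applied to odd readout lines (Nyquist-ghost model).
#' @param ets_us echo-time shift per segment, microseconds.
#' @param seed integer RNG seed for the noise stream.
#' @return object of class `acquisition_params`.
#' @export
acquisition_params <- function(fa = 90, tr = 261, te_list = c(9, 21.5, 34),
                               n_segments = 4L, fov_shift_factor = 4L,
                               mb = 4L, noise_sd = 0,
                               ghost_phase = c(0, 0), ets_us = 150,
                               seed = 1L) {
  stopifnot(fa > 0, fa <= 90, tr > 0, all(te_list > 0),
            n_segments >= 1, fov_shift_factor >= 1, mb >= 1,
            noise_sd >= 0, length(ghost_phase) == 2, ets_us >= 0)
  if (is.unsorted(te_list, strictly = TRUE)) {
    stop("te_list must be strictly increasing")
  }
  structure(list(fa = fa, tr = tr, te_list = te_list,
                 n_segments = as.integer(n_segments),
                 fov_shift_factor = as.integer(fov_shift_factor),
                 mb = as.integer(mb), noise_sd = noise_sd,
                 ghost_phase = ghost_phase, ets_us = ets_us,
                 seed = as.integer(seed)),
            class = "acquisition_params")
}

#' Per-line CAIPIRINHA modulation factors
#'
#' The complex factor `exp(2i pi ky n / f)` applied to 0-based k-space line
#' `ky` of group-slice `n` when collapsing slices. On the lines of one
#' segment it equals the constant [caipi_phase()] whenever the combination
#' is realizable.
#'
#' @param n group-slice index, 0-based.
#' @param f FOV shift factor.
#' @param n_pe number of phase-encode lines.
#' @return complex vector of length `n_pe`.
#' @export
caipi_line_phase <- function(n, f, n_pe) {
  exp(2i * pi * (0:(n_pe - 1)) * n / f)
}

# 0-based ky rows with negative readout polarity: within a segment the
# readout direction alternates per acquired line, and line ky belongs to
# acquired-train position floor(ky / n_segments).
negative_polarity_rows <- function(n_pe, n_segments) {
  ky <- 0:(n_pe - 1)
  which((ky %/% n_segments) %% 2L == 1L)  # 1-based row indices
}

# apply the odd/even ghost phase (constant + linear in readout sample)
# to the given rows of a [ky, kx] k-space matrix, in hybrid (ky, x) space
apply_ghost_rows <- function(K, rows, phase) {
  if (length(rows) == 0 || all(phase == 0)) return(K)
  nx <- ncol(K)
  x <- (0:(nx - 1)) - floor(nx / 2)
  ramp <- exp(1i * (phase[1] + phase[2] * x))
  for (r in rows) {
    K[r, ] <- ft1(ift1(K[r, ]) * ramp)
  }
  K
}

new_kspace_set <- function(kspace, navigators, plan, params, type, slice_map) {
  structure(list(kspace = kspace, navigators = navigators, plan = plan,
                 params = params, type = type, slice_map = slice_map),
            class = "kspace_set")
}

#' @export
print.kspace_set <- function(x, ...) {
  d <- dim(x$kspace)
  cat(sprintf(
    "<kspace_set> %s: %d frame(s) x %d group(s) x %d echo(es) x %d coil(s), %d x %d k-space\n",
    x$type, d[6], d[5], d[4], d[3], d[1], d[2]))
  invisible(x)
}

#' Simulate a multi-echo segmented-EPI acquisition
#'
#' Encodes one or more phantom volumes into multi-coil k-space following
#' the multiband segmented-EPI scheme: for every slice, echo and segment
#' the spoiled-GRE signal is evaluated at the segment's effective echo time
#' (nominal TE + segment index x ETS), weighted by the coil sensitivities
#' and Fourier transformed; segment `i` contributes ky lines
#' `i, i + n_segments, ...`. With `mb > 1` the slices of each multiband
#' group are summed coherently with the per-line CAIPIRINHA phases of the
#' plan. Odd-polarity readout lines optionally receive a Nyquist-ghost
#' phase (constant + linear in the readout sample), and i.i.d. complex
#' Gaussian noise is added with the seeded RNG. Three navigator lines
#' (positive, negative, positive readout polarity; no phase encoding) are
#' recorded per group from the first-echo DC projection.
#'
#' Slice-to-group mapping: group `g` (1-based) contains slices
#' `g, g + n_groups, ..., g + (mb-1) n_groups`, i.e. the slices of a group
#' are equally spaced across the volume.
#'
#' @param volumes a `phantom_volume`, or a list of them (one per frame).
#' @param coils a `coil_maps` whose grid and slice count match the volume.
#' @param plan a [plan()] consistent with `params`.
#' @param params an [acquisition_params()].
#' @return a `kspace_set` with complex array `kspace`
#'   `[ky, kx, coil, echo, group, frame]` and `navigators`
#'   `[kx, 3, coil, group, frame]`.
#' @export
encode_acquisition <- function(volumes, coils, plan, params) {
  if (inherits(volumes, "phantom_volume")) volumes <- list(volumes)
  stopifnot(inherits(coils, "coil_maps"), inherits(plan, "sequence_plan"),
            inherits(params, "acquisition_params"))
  if (params$n_segments != plan$n_segments ||
      params$mb != plan$mb ||
      params$fov_shift_factor != plan$f ||
      !isTRUE(all.equal(params$te_list, plan$te_nominal))) {
    stop("plan/params mismatch (segments, mb, shift factor or echo times)")
  }
  vol1 <- volumes[[1]]
  nz <- vol1$grid_shape[1]; ny <- vol1$grid_shape[2]; nx <- vol1$grid_shape[3]
  if (plan$n_slices != nz) stop("plan n_slices does not match the volume")
  if (plan$n_pe != ny) stop("plan n_pe must equal the PE matrix size ny")
  if (!all(coils$grid == c(ny, nx)) || coils$n_slices != nz) {
    stop("coil map grid does not match the volume")
  }
  n_frames <- length(volumes)
  nc <- coils$n_coils
  ne <- length(params$te_list)
  mb <- params$mb
  ng <- plan$n_groups
  ns <- plan$n_segments
  f <- plan$f

  slice_map <- outer(seq_len(ng), 0:(mb - 1), function(g, n) g + n * ng)
  ks <- array(0i, dim = c(ny, nx, nc, ne, ng, n_frames))
  navs <- array(0i, dim = c(nx, 3, nc, ng, n_frames))
  neg_rows <- negative_polarity_rows(ny, ns)
  dc_row <- floor(ny / 2) + 1L
  x <- (0:(nx - 1)) - floor(nx / 2)
  nav_ramp <- exp(1i * (params$ghost_phase[1] + params$ghost_phase[2] * x))

  for (fr in seq_len(n_frames)) {
    vol <- volumes[[fr]]
    for (g in seq_len(ng)) {
      for (n in 0:(mb - 1)) {
        z <- slice_map[g, n + 1]
        ph <- if (mb > 1) caipi_line_phase(n, f, ny) else rep(1 + 0i, ny)
        for (e in seq_len(ne)) {
          for (i in seq_len(ns)) {
            te_eff <- plan$te_effective[i, e]
            sig <- matrix(0, ny, nx)
            obj <- vol$pd[z, , ] > 0
            sig[obj] <- spgr_signal(vol$pd[z, , ][obj], vol$t1[z, , ][obj],
                                    vol$t2s[z, , ][obj],
                                    fa = params$fa, tr = params$tr, te = te_eff)
            rows <- plan$segment_lines[[i]] + 1L
            for (cc in seq_len(nc)) {
              K <- ft2(sig * coils$maps[, , cc, z])
              ks[rows, , cc, e, g, fr] <- ks[rows, , cc, e, g, fr] +
                K[rows, , drop = FALSE] * ph[rows]
              if (e == 1 && i == 1) {
                # navigator: first-echo DC projection, no CAIPIRINHA phase
                navs[, 1, cc, g, fr] <- navs[, 1, cc, g, fr] + K[dc_row, ]
                navs[, 3, cc, g, fr] <- navs[, 3, cc, g, fr] + K[dc_row, ]
                navs[, 2, cc, g, fr] <- navs[, 2, cc, g, fr] +
                  ft1(ift1(K[dc_row, ]) * nav_ramp)
              }
            }
          }
        }
      }
      if (any(params$ghost_phase != 0)) {
        for (e in seq_len(ne)) {
          for (cc in seq_len(nc)) {
            ks[, , cc, e, g, fr] <- apply_ghost_rows(ks[, , cc, e, g, fr],
                                                     neg_rows,
                                                     params$ghost_phase)
          }
        }
      }
    }
  }

  if (params$noise_sd > 0) {
    with_seed(params$seed, {
      ks <- ks + array(complex_noise(length(ks), params$noise_sd), dim = dim(ks))
      navs <- navs + array(complex_noise(length(navs), params$noise_sd),
                           dim = dim(navs))
    })
  }

  new_kspace_set(ks, navs, plan, params,
                 type = if (mb > 1) "sms" else "sb", slice_map = slice_map)
}

#' Collapse single-band k-space into synthesized multiband groups
#'
#' Builds SMS data from a single-band acquisition by summing, for every
#' multiband group, the k-spaces of its member slices with the per-line
#' CAIPIRINHA phases of `plan` (this is how "method 2" ACS source data are
#' synthesized). The operation is exactly linear in its input; on
#' noiseless data it reproduces a directly simulated SMS acquisition.
#'
#' @param sb a single-band `kspace_set` (mb = 1) containing all slices.
#' @param plan the SMS [plan()] (defines mb, f and the group mapping).
#' @return an SMS `kspace_set`.
#' @export
collapse_slices <- function(sb, plan) {
  stopifnot(inherits(sb, "kspace_set"), inherits(plan, "sequence_plan"))
  if (sb$type != "sb") stop("collapse_slices expects single-band input")
  d <- dim(sb$kspace)
  ny <- d[1]; nx <- d[2]; nc <- d[3]; ne <- d[4]; nslice <- d[5]; nf <- d[6]
  mb <- plan$mb; ng <- plan$n_groups
  if (nslice != plan$n_slices) stop("missing slices: single-band set has ",
                                    nslice, ", plan expects ", plan$n_slices)
  slice_map <- outer(seq_len(ng), 0:(mb - 1), function(g, n) g + n * ng)
  ks <- array(0i, dim = c(ny, nx, nc, ne, ng, nf))
  navs <- array(0i, dim = c(nx, 3, nc, ng, nf))
  for (g in seq_len(ng)) {
    for (n in 0:(mb - 1)) {
      z <- slice_map[g, n + 1]
      ph <- caipi_line_phase(n, plan$f, ny)
      ks[, , , , g, ] <- ks[, , , , g, ] +
        sweep(sb$kspace[, , , , z, , drop = FALSE], 1, ph, "*")[, , , , 1, ]
      navs[, , , g, ] <- navs[, , , g, ] + sb$navigators[, , , z, ]
    }
  }
  params <- sb$params
  params$mb <- as.integer(mb)
  params$fov_shift_factor <- as.integer(plan$f)
  new_kspace_set(ks, navs, plan, params, type = "sms", slice_map = slice_map)
}

#' Direct reference reconstruction of single-band data
#'
#' Inverse-FFT and sum-of-squares combination per slice and echo; the
#' reference `I_SB` against which SMS reconstructions are compared.
#'
#' @param sb a single-band `kspace_set`.
#' @param frame frame index.
#' @return magnitude array `[ny, nx, slice, echo]`.
#' @export
sb_reference_images <- function(sb, frame = 1L) {
  stopifnot(sb$type == "sb")
  d <- dim(sb$kspace)
  out <- array(0, dim = c(d[1], d[2], d[5], d[4]))
  for (z in seq_len(d[5])) {
    for (e in seq_len(d[4])) {
      ci <- array(0i, dim = c(d[1], d[2], d[3]))
      for (cc in seq_len(d[3])) ci[, , cc] <- ift2(sb$kspace[, , cc, e, z, frame])
      out[, , z, e] <- sos_combine(ci)
    }
  }
  out
}
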