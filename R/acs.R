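#' Downsample autocalibration data to a low-resolution central k-space block
#'
#' Crops the central (DC-preserving) block of k-space, emulating the use of
#' low-resolution training data for kernel calibration (64 x 64 by default).
#' With the package's centered conventions the DC sample at 0-based index
#' `floor(N/2)` stays the DC sample of the cropped grid. Cropping never
#' increases energy. Methods exist for plain arrays (first two dims ky, kx),
#' for `kspace_set` and for `acs_pair` objects.
#'
#' @param x array, `kspace_set` or `acs_pair`.
#' @param target_grid integer pair `(ky, kx)`, each <= the source grid.
#' @return same class as `x`, cropped.
#' @export
downsample_acs <- function(x, target_grid = c(64L, 64L)) {
  UseMethod("downsample_acs")
}

crop_idx <- function(n, t) {
  if (t > n) stop("target grid larger than source (", t, " > ", n, ")")
  start <- floor(n / 2) + 1L - floor(t / 2)   # 1-based
  start:(start + t - 1L)
}

#' @export
downsample_acs.array <- function(x, target_grid = c(64L, 64L)) {
  d <- dim(x)
  ridx <- crop_idx(d[1], target_grid[1])
  cidx <- crop_idx(d[2], target_grid[2])
  idx <- c(list(ridx, cidx), lapply(d[-(1:2)], seq_len))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @export
downsample_acs.matrix <- function(x, target_grid = c(64L, 64L)) {
  x[crop_idx(nrow(x), target_grid[1]), crop_idx(ncol(x), target_grid[2]),
    drop = FALSE]
}

#' @export
downsample_acs.kspace_set <- function(x, target_grid = c(64L, 64L)) {
  x$kspace <- downsample_acs.array(x$kspace, target_grid)
  x$navigators <- NULL  # navigators are full-resolution readouts; dropped
  x
}

#' @export
downsample_acs.acs_pair <- function(x, target_grid = c(64L, 64L)) {
  x$source <- downsample_acs.array(x$source, target_grid)
  x$target <- downsample_acs.array(x$target, target_grid)
  x
}

acs_contrast <- function(params) {
  list(te_list = params$te_list, fa = params$fa, tr = params$tr)
}

new_acs_pair <- function(source, target, method, contrast, mb, f, n_groups) {
  structure(list(source = source, target = target, method = method,
                 contrast = contrast, mb = mb, f = f, n_groups = n_groups),
            class = "acs_pair")
}

#' Prepare ACS training data, method 1 (measured SMS source)
#'
#' ACS target data are the single-band slices with their CAIPIRINHA
#' phase-encode shifts applied; ACS source data are a measured (or directly
#' simulated) SMS acquisition. Both acquisitions must share the contrast
#' parameters (TE, FA, TR): a mismatch is an error, since kernel weights
#' depend on the underlying image contrast.
#'
#' @param sms_acs SMS `kspace_set` (the measured collapsed ACS source).
#' @param sb_acs single-band `kspace_set` with all slices (ACS target).
#' @param plan the SMS [plan()].
#' @param frame frame index of the ACS sets to use.
#' @return an `acs_pair` with `source[ky, kx, coil, echo, group]` and
#'   `target[ky, kx, coil, slice-in-group, echo, group]`.
#' @export
prepare_acs_method1 <- function(sms_acs, sb_acs, plan, frame = 1L) {
  stopifnot(inherits(sms_acs, "kspace_set"), inherits(sb_acs, "kspace_set"))
  if (sms_acs$type != "sms" || sb_acs$type != "sb") {
    stop("method 1 needs an SMS source set and a single-band target set")
  }
  ca <- acs_contrast(sms_acs$params); cb <- acs_contrast(sb_acs$params)
  if (!isTRUE(all.equal(ca, cb))) {
    stop("contrast mismatch: ACS source and target must share TE, FA and TR")
  }
  target <- phased_targets(sb_acs, plan, frame)
  source <- sms_acs$kspace[, , , , , frame, drop = FALSE]
  dim(source) <- dim(source)[1:5]
  new_acs_pair(source, target, method = 1L, contrast = ca,
               mb = plan$mb, f = plan$f, n_groups = plan$n_groups)
}

#' Prepare ACS training data, method 2 (synthesized source)
#'
#' Both source and target come from the same single-band acquisition: the
#' targets are the CAIPIRINHA-shifted slices and the source is synthesized
#' by collapsing them ([collapse_slices()] semantics). This is the only
#' ACS form usable by split slice-GRAPPA, which needs per-slice sources.
#'
#' @inheritParams prepare_acs_method1
#' @return an `acs_pair` with `method = 2`.
#' @export
prepare_acs_method2 <- function(sb_acs, plan, frame = 1L) {
  stopifnot(inherits(sb_acs, "kspace_set"))
  if (sb_acs$type != "sb") stop("method 2 needs a single-band set")
  if (dim(sb_acs$kspace)[5] != plan$n_slices) {
    stop("missing slices in the single-band ACS set")
  }
  target <- phased_targets(sb_acs, plan, frame)
  # source = sum over group slices of the phased targets
  source <- array(0i, dim = dim(target)[c(1:3, 5:6)])
  for (n in seq_len(plan$mb)) {
    tn <- target[, , , n, , , drop = FALSE]
    dim(tn) <- dim(target)[c(1:3, 5:6)]
    source <- source + tn
  }
  new_acs_pair(source, target, method = 2L,
               contrast = acs_contrast(sb_acs$params),
               mb = plan$mb, f = plan$f, n_groups = plan$n_groups)
}

# CAIPIRINHA-shifted per-slice targets [ky, kx, coil, n, echo, group]
phased_targets <- function(sb_acs, plan, frame = 1L) {
  d <- dim(sb_acs$kspace)
  ny <- d[1]; nx <- d[2]; nc <- d[3]; ne <- d[4]
  mb <- plan$mb; ng <- plan$n_groups
  if (d[5] != plan$n_slices) stop("missing slices in single-band set")
  slice_map <- outer(seq_len(ng), 0:(mb - 1), function(g, n) g + n * ng)
  target <- array(0i, dim = c(ny, nx, nc, mb, ne, ng))
  for (g in seq_len(ng)) {
    for (n in 0:(mb - 1)) {
      z <- slice_map[g, n + 1]
      ph <- caipi_line_phase(n, plan$f, ny)
      for (e in seq_len(ne)) {
        for (cc in seq_len(nc)) {
          target[, , cc, n + 1, e, g] <- sb_acs$kspace[, , cc, e, z, frame] * ph
        }
      }
    }
  }
  target
}
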