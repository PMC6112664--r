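#' Phantom configuration
#'
#' Describes a structured digital phantom: an elliptical main body with
#' relaxation times typical of a contrast-agent doped agar phantom
#' (background T1 = 289 ms) containing circular sub-volumes doped to a
#' range of T1 values (211 / 434 / 556 / 953 / 1257 ms by default) plus an
#' optional small "vessel" compartment used by the dynamic contrast-agent
#' simulation. All geometry is given in fractions of the in-plane grid so
#' the same configuration scales to any matrix size. The sub-volume ring is
#' rotated by a per-slice angle so that simultaneously excited slices have
#' distinct structure.
#'
#' The paper-derived T1 values are fixed defaults; T2* values are a design
#' choice of this package (no published values exist for that phantom):
#' background 50 ms, sub-volumes 20/35/50/70/90 ms, vessel 100 ms.
#'
#' @param grid_shape integer triple `(nz, ny, nx)`.
#' @param voxel_size mm triple, default `c(5, 3.1, 3.1)`.
#' @param background list with `t1`, `t2s`, `pd` of the main body.
#' @param subvols data.frame with one row per sub-volume: columns `label`,
#'   `t1`, `t2s`, `pd`, `cy`, `cx` (center, fraction of grid), `r` (radius,
#'   fraction of min(ny, nx)). Pass a 0-row data.frame for a uniform phantom.
#' @param vessel `NULL` or list `(t1, t2s, pd, cy, cx, r)`; labelled as the
#'   vascular compartment for the bolus model.
#' @param slice_rotation radians of sub-volume ring rotation per slice.
#' @return an object of class `phantom_spec`.
#' @seealso [build_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(4L, 64L, 64L),
                         voxel_size = c(5, 3.1, 3.1),
                         background = list(t1 = 289, t2s = 50, pd = 100),
                         subvols = default_subvols(),
                         vessel = list(t1 = 1200, t2s = 100, pd = 120,
                                       cy = 0.5, cx = 0.5, r = 0.05),
                         slice_rotation = 0.7) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  if (nrow(subvols) > 0) {
    stopifnot(all(c("label", "t1", "t2s", "pd", "cy", "cx", "r") %in%
                    names(subvols)))
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, background = background,
                 subvols = subvols, vessel = vessel,
                 slice_rotation = slice_rotation),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_subvols <- function() {
  k <- 5
  ang <- 2 * pi * (seq_len(k) - 1) / k - pi / 2
  data.frame(label = 2:6,
             t1 = c(211, 434, 556, 953, 1257),
             t2s = c(20, 35, 50, 70, 90),
             pd = c(50, 80, 110, 140, 170),
             cy = 0.5 + 0.26 * sin(ang),
             cx = 0.5 + 0.26 * cos(ang),
             r = 0.10)
}

#' Build a digital phantom volume
#'
#' Voxelizes a [phantom_spec()] onto its grid, producing per-voxel proton
#' density, T1 and T2* maps plus an integer compartment label map.
#' Label 0 is outside the object (pd = 0), label 1 the phantom body,
#' labels from `subvols` the doped sub-volumes, and the vessel (if present)
#' the highest label. Sub-volumes and the vessel overwrite the body;
#' overlapping sub-volumes with conflicting parameter values are an error
#' naming the colliding labels. Deterministic: no randomness is involved.
#'
#' @param spec a `phantom_spec`.
#' @return object of class `phantom_volume` with fields `grid_shape`,
#'   `voxel_size`, `pd`, `t1`, `t2s`, `labels` (arrays `nz x ny x nx`) and
#'   `classes` (named character vector, label -> "tissue"/"vessel").
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  nz <- gs[1]; ny <- gs[2]; nx <- gs[3]
  dim3 <- c(nz, ny, nx)
  pd <- array(0, dim3); t1 <- array(1, dim3); t2s <- array(1, dim3)
  labels <- array(0L, dim3)

  yy <- matrix((seq_len(ny) - 0.5) / ny, ny, nx)
  xx <- matrix((seq_len(nx) - 0.5) / nx, ny, nx, byrow = TRUE)
  rmin <- min(ny, nx) / max(ny, nx)  # not used for discs; kept isotropic below

  body <- ((yy - 0.5) / 0.42)^2 + ((xx - 0.5) / 0.42)^2 <= 1

  rot <- function(cy, cx, th) {
    v <- c(cy, cx) - 0.5
    0.5 + c(cos(th) * v[1] - sin(th) * v[2],
            sin(th) * v[1] + cos(th) * v[2])
  }

  for (z in seq_len(nz)) {
    th <- (z - 1) * spec$slice_rotation
    lab <- matrix(0L, ny, nx)
    lab[body] <- 1L
    t1z <- matrix(spec$background$t1, ny, nx)
    t2z <- matrix(spec$background$t2s, ny, nx)
    pdz <- matrix(spec$background$pd, ny, nx)

    shapes <- list()
    if (nrow(spec$subvols) > 0) {
      for (k in seq_len(nrow(spec$subvols))) {
        s <- spec$subvols[k, ]
        cc <- rot(s$cy, s$cx, th)
        inside <- (yy - cc[1])^2 + (xx - cc[2])^2 <= s$r^2
        shapes[[length(shapes) + 1]] <-
          list(label = s$label, inside = inside & body,
               t1 = s$t1, t2s = s$t2s, pd = s$pd)
      }
    }
    if (!is.null(spec$vessel)) {
      v <- spec$vessel
      inside <- (yy - v$cy)^2 + (xx - v$cx)^2 <= v$r^2
      shapes[[length(shapes) + 1]] <-
        list(label = max(c(1L, spec$subvols$label)) + 1L,
             inside = inside & body, t1 = v$t1, t2s = v$t2s, pd = v$pd)
    }

    if (length(shapes) > 1) {
      for (a in seq_len(length(shapes) - 1)) {
        for (b in (a + 1):length(shapes)) {
          ov <- shapes[[a]]$inside & shapes[[b]]$inside
          same <- shapes[[a]]$t1 == shapes[[b]]$t1 &&
            shapes[[a]]$t2s == shapes[[b]]$t2s &&
            shapes[[a]]$pd == shapes[[b]]$pd
          if (any(ov) && !same) {
            stop(sprintf(
              "overlapping sub-volumes with conflicting values: labels %d and %d",
              shapes[[a]]$label, shapes[[b]]$label))
          }
        }
      }
    }
    for (s in shapes) {
      lab[s$inside] <- as.integer(s$label)
      t1z[s$inside] <- s$t1
      t2z[s$inside] <- s$t2s
      pdz[s$inside] <- s$pd
    }
    pdz[!body] <- 0

    labels[z, , ] <- lab
    t1[z, , ] <- t1z
    t2s[z, , ] <- t2z
    pd[z, , ] <- pdz
  }

  classes <- c("1" = "tissue")
  if (nrow(spec$subvols) > 0) {
    classes <- c(classes,
                 stats::setNames(rep("tissue", nrow(spec$subvols)),
                                 spec$subvols$label))
  }
  if (!is.null(spec$vessel)) {
    vlab <- max(c(1L, spec$subvols$label)) + 1L
    classes <- c(classes, stats::setNames("vessel", vlab))
  }

  structure(list(grid_shape = gs, voxel_size = spec$voxel_size,
                 pd = pd, t1 = t1, t2s = t2s, labels = labels,
                 classes = classes, spec = spec),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %d x %d x %d voxels (%.3g%% object)\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              100 * mean(x$labels > 0)))
  cat("  compartments:", paste(sort(unique(as.vector(x$labels))),
                               collapse = " "), "\n")
  invisible(x)
}

#' Ground-truth base signal and echo images of a phantom
#'
#' `phantom_s0_map()` evaluates the SPGR base signal (TE = 0) per voxel;
#' `phantom_echo_image()` the full signal at one echo time. Used as the
#' noise-free reference in reconstruction-quality tests.
#'
#' @param vol a `phantom_volume`.
#' @param fa,tr,te acquisition parameters (degrees, ms, ms).
#' @return array `nz x ny x nx`.
#' @export
phantom_s0_map <- function(vol, fa, tr) {
  out <- vol$pd * 0
  obj <- vol$pd > 0
  out[obj] <- spgr_signal(vol$pd[obj], vol$t1[obj], vol$t2s[obj],
                          fa = fa, tr = tr, te = 0)
  out
}

#' @rdname phantom_s0_map
#' @export
phantom_echo_image <- function(vol, fa, tr, te) {
  out <- vol$pd * 0
  obj <- vol$pd > 0
  out[obj] <- spgr_signal(vol$pd[obj], vol$t1[obj], vol$t2s[obj],
                          fa = fa, tr = tr, te = te)
  out
}
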