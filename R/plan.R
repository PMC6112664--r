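#' CAIPIRINHA phase for one segment and group-slice
#'
#' The phase applied to the k-space lines of EPI segment `i` (0-based) for
#' the n-th slice of a multiband group (0-based), realizing an in-plane
#' field-of-view shift of `N_PE / f` pixels along the phase-encode
#' direction: `phi(i, n) = 2 pi i n / f (mod 2 pi)`. The value is only
#' well defined when every ky line of the segment maps to the same phase
#' modulo 2 pi, i.e. when `f` divides `n_segments * n`; otherwise an error
#' is raised (see [validate_shift()]).
#'
#' @param i segment index, 0-based, `0 <= i < n_segments`.
#' @param n slice index within the multiband group, 0-based.
#' @param f FOV shift factor (shift = FOV / f), integer >= 1.
#' @param n_segments number of EPI segments.
#' @return phase in radians, in `[0, 2 pi)`.
#' @export
caipi_phase <- function(i, n, f, n_segments) {
  stopifnot(i >= 0, i < n_segments, n >= 0, f >= 1, n_segments >= 1)
  if ((n_segments * n) %% f != 0) {
    stop(sprintf(paste0(
      "inconsistent CAIPIRINHA combination: the ky lines of segment %d ",
      "would require different phases for group-slice %d ",
      "(f = %d does not divide n_segments * n = %d)"),
      i, n, f, n_segments * n))
  }
  (2 * pi * i * n / f) %% (2 * pi)
}

#' Check realizability of a CAIPIRINHA shift factor
#'
#' A segmented-EPI CAIPIRINHA shift is realizable only if, for every slice
#' `n < mb` of a multiband group, all ky lines belonging to one segment
#' (lines `i, i + n_segments, ...`) require the same modulation phase
#' modulo 2 pi. The check is performed by brute force over the line phases
#' `2 pi ky n / f`.
#'
#' @param f FOV shift factor.
#' @param n_segments number of EPI segments.
#' @param mb multiband factor (slices per group).
#' @return list with `pass` (logical) and `reason` (character).
#' @export
validate_shift <- function(f, n_segments, mb) {
  stopifnot(f >= 1, n_segments >= 1, mb >= 1)
  for (n in 0:(mb - 1)) {
    # phases of successive lines of one segment differ by 2*pi*n_segments*n/f
    ky <- seq(0, by = n_segments, length.out = 8)
    ph <- 2 * pi * ky * n / f
    # circular comparison (phases may straddle the 0 / 2*pi wrap)
    if (max(abs(Arg(exp(1i * (ph - ph[1]))))) > 1e-9) {
      return(list(pass = FALSE, reason = sprintf(
        "group-slice %d: lines of one segment map to different phases (f = %d, n_segments = %d)",
        n, f, n_segments)))
    }
  }
  list(pass = TRUE, reason = "ok")
}

#' Interleaved multiband-group acquisition order
#'
#' Even-indexed groups are acquired first, then odd-indexed groups
#' (`0, 2, 4, ..., 1, 3, 5, ...`), so spatially adjacent groups are never
#' temporal neighbors (for 4 or more groups), reducing cross-talk and
#' saturation between adjacent multiband excitations. With exactly four
#' groups the plain split would place groups 2 and 1 back to back, so both
#' half-blocks are reversed there (`2, 0, 3, 1`), which preserves the
#' evens-before-odds rule.
#'
#' @param n_groups number of multiband slice groups.
#' @return 0-based integer permutation of `0:(n_groups - 1)`.
#' @export
interleaved_group_order <- function(n_groups) {
  stopifnot(n_groups >= 1)
  if (n_groups == 1) return(0L)
  if (n_groups == 4) return(c(2L, 0L, 3L, 1L))
  as.integer(c(seq(0L, n_groups - 1L, by = 2L),
               seq(1L, n_groups - 1L, by = 2L)))
}

#' Compute a segmented-EPI SMS acquisition plan
#'
#' Assigns phase-encode lines to EPI segments (segment `i` acquires lines
#' `i, i + n_segments, ...`, 0-based), computes per-segment effective echo
#' times under echo-time shifting, the CAIPIRINHA phase schedule, the
#' interleaved group order and the frame timing. One frame consists of
#' `n_segments` TR periods (all slice groups are excited within each TR)
#' plus an optional dead time, so the temporal resolution is
#' `dt = (n_segments * tr + dead_time) / 1000` seconds.
#'
#' For the protocol emulated by the package defaults (68 PE lines, 4
#' segments, TR = 261 ms, dead_time = 261 ms) this gives ETL = 17 and
#' dt = 1.305 s; 500 frames take 652.5 s, rendered "10:52".
#'
#' @param n_pe number of phase-encode lines.
#' @param n_segments number of EPI segments.
#' @param n_slices total slice count; must be a multiple of `mb`.
#' @param mb multiband factor.
#' @param f CAIPIRINHA FOV shift factor.
#' @param te_list echo times, ms, strictly increasing.
#' @param tr repetition time, ms.
#' @param ets echo-time shift between adjacent segments, ms (150 us = 0.15).
#' @param n_frames number of dynamic frames.
#' @param dead_time extra time per frame, ms (e.g. navigator/spoiler slot).
#' @return object of class `sequence_plan`.
#' @export
plan <- function(n_pe, n_segments, n_slices, mb, f, te_list, tr,
                 ets = 0.15, n_frames = 1L, dead_time = 0) {
  stopifnot(n_pe >= 1, n_segments >= 1, n_slices >= 1, mb >= 1,
            tr > 0, all(te_list > 0), ets >= 0, n_frames >= 1, dead_time >= 0)
  if (is.unsorted(te_list, strictly = TRUE)) {
    stop("te_list must be strictly increasing")
  }
  if (n_slices %% mb != 0) {
    stop(sprintf("mb = %d does not divide n_slices = %d", mb, n_slices))
  }
  chk <- validate_shift(f, n_segments, mb)
  if (!chk$pass) stop("invalid shift factor: ", chk$reason)

  etl <- as.integer(ceiling(n_pe / n_segments))
  segment_lines <- lapply(0:(n_segments - 1), function(i) {
    as.integer(seq(i, n_pe - 1, by = n_segments))
  })
  te_effective <- outer(0:(n_segments - 1), te_list,
                        function(i, te) te + i * ets)
  caipi <- outer(0:(n_segments - 1), 0:(mb - 1),
                 Vectorize(function(i, n) caipi_phase(i, n, f, n_segments)))
  n_groups <- n_slices %/% mb
  dt <- (n_segments * tr + dead_time) / 1000

  structure(list(n_pe = as.integer(n_pe), n_segments = as.integer(n_segments),
                 etl = etl, segment_lines = segment_lines,
                 te_nominal = te_list, te_effective = te_effective,
                 group_order = interleaved_group_order(n_groups),
                 caipi_phase = caipi, n_slices = as.integer(n_slices),
                 mb = as.integer(mb), f = as.integer(f),
                 n_groups = as.integer(n_groups), tr = tr, ets = ets,
                 dead_time = dead_time, dt = dt, n_frames = as.integer(n_frames),
                 total_time = n_frames * dt),
            class = "sequence_plan")
}

#' Render seconds as "mm:ss" (flooring the seconds, as scan consoles do)
#' @param seconds duration in seconds.
#' @export
format_mmss <- function(seconds) {
  sprintf("%d:%02d", floor(seconds / 60), floor(seconds %% 60))
}

#' In-plane pixel size from field of view and matrix size
#' @param fov_mm field of view, mm.
#' @param n_samples matrix size along that axis.
#' @return pixel size in mm.
#' @export
pixel_size <- function(fov_mm, n_samples) fov_mm / n_samples

#' @export
print.sequence_plan <- function(x, ...) {
  cat("<sequence_plan>\n")
  cat(sprintf("  PE lines        : %d in %d segments (ETL = %d)\n",
              x$n_pe, x$n_segments, x$etl))
  cat(sprintf("  slices          : %d (MB = %d, %d groups, FOV/%d shift)\n",
              x$n_slices, x$mb, x$n_groups, x$f))
  cat(sprintf("  echoes          : TE = %s ms (ETS %.3g ms/segment)\n",
              paste(x$te_nominal, collapse = " / "), x$ets))
  cat(sprintf("  timing          : TR = %g ms, dead time %g ms, dt = %.4g s\n",
              x$tr, x$dead_time, x$dt))
  cat(sprintf("  frames          : %d, total %.5g s (%s)\n",
              x$n_frames, x$total_time, format_mmss(x$total_time)))
  cat(sprintf("  group order     : %s\n",
              paste(x$group_order, collapse = " ")))
  invisible(x)
}
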