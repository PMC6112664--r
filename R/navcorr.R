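#' Nyquist-ghost phase estimation and correction from navigator lines
#'
#' Segmented EPI alternates the readout gradient polarity between acquired
#' lines; timing misalignment imprints a constant plus linear phase on the
#' negative-polarity lines, producing `N_seg` ghosts along the phase-encode
#' direction. Three navigator lines without phase encoding (positive,
#' negative, positive polarity) are used to estimate that phase: the two
#' positive projections are averaged, the linear slope is the mean phase
#' increment of `neg * Conj(pos)` across readout samples (magnitude-weighted
#' autocorrelation estimator), and the constant term is the residual global
#' phase. The estimated phase is then removed from all odd-polarity lines
#' in hybrid (ky, x) space.
#'
#' @param kspace complex array `[ky, kx]` or `[ky, kx, coil]` of one
#'   group/echo, or `[ky, kx, coil, echo]`.
#' @param navigators complex array `[kx, 3, coil]` (`[kx, 3]` for one coil);
#'   columns are +, -, + polarity. `NULL` issues a warning and returns the
#'   input unchanged.
#' @param n_segments number of EPI segments (defines which ky lines have
#'   negative polarity: `floor(ky / n_segments)` odd, 0-based).
#' @return corrected array, same shape as `kspace`.
#' @export
navigator_phase_correct <- function(kspace, navigators, n_segments) {
  if (is.null(navigators)) {
    warning("navigator lines missing; phase correction skipped")
    return(kspace)
  }
  est <- estimate_nav_phase(navigators)
  correct_ghost_phase(kspace, est, n_segments)
}

#' @rdname navigator_phase_correct
#' @return `estimate_nav_phase()` returns `c(constant, slope)` in radians
#'   and radians/sample.
#' @export
estimate_nav_phase <- function(navigators) {
  if (length(dim(navigators)) == 2) {
    dim(navigators) <- c(dim(navigators), 1L)
  }
  nx <- dim(navigators)[1]
  nc <- dim(navigators)[3]
  x <- (0:(nx - 1)) - floor(nx / 2)
  acc_slope <- 0i
  d_all <- matrix(0i, nx, nc)
  for (cc in seq_len(nc)) {
    pos <- ift1((navigators[, 1, cc] + navigators[, 3, cc]) / 2)
    neg <- ift1(navigators[, 2, cc])
    d <- neg * Conj(pos)
    d_all[, cc] <- d
    acc_slope <- acc_slope + sum(d[-1] * Conj(d[-nx]))
  }
  slope <- Arg(acc_slope)
  const <- Arg(sum(d_all * exp(-1i * slope * x)))
  c(constant = const, slope = slope)
}

#' @rdname navigator_phase_correct
#' @param phase numeric pair `(constant, slope)` as from
#'   `estimate_nav_phase()`.
#' @export
correct_ghost_phase <- function(kspace, phase, n_segments) {
  d <- dim(kspace)
  ny <- d[1]; nx <- d[2]
  rows <- negative_polarity_rows(ny, n_segments)
  if (length(rows) == 0 || all(phase == 0)) return(kspace)
  x <- (0:(nx - 1)) - floor(nx / 2)
  ramp <- exp(-1i * (phase[1] + phase[2] * x))
  planes <- prod(d[-(1:2)], 1)
  dim(kspace) <- c(ny, nx, planes)
  for (p in seq_len(planes)) {
    for (r in rows) {
      kspace[r, , p] <- ft1(ift1(kspace[r, , p]) * ramp)
    }
  }
  dim(kspace) <- d
  kspace
}
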