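#' Multi-echo series container
#'
#' Magnitude signals of a multi-echo acquisition over frames, as produced
#' by [as_echo_series()] from a reconstruction, or assembled directly.
#'
#' @param te_list echo times, ms, strictly increasing, length >= 2.
#' @param signals numeric array `[frame, echo, ...spatial]`, >= 0.
#' @param frame_times acquisition times of the frames, s.
#' @return object of class `echo_series`.
#' @export
echo_series <- function(te_list, signals, frame_times = NULL) {
  stopifnot(length(te_list) >= 2, !is.unsorted(te_list, strictly = TRUE))
  d <- dim(signals)
  stopifnot(length(d) >= 2, d[2] == length(te_list))
  if (is.null(frame_times)) frame_times <- seq_len(d[1]) - 1
  stopifnot(length(frame_times) == d[1])
  structure(list(te_list = te_list, signals = signals,
                 frame_times = frame_times),
            class = "echo_series")
}

#' @rdname echo_series
#' @param recon a `recon_result` with frame dimension
#'   (`[ny, nx, slice, echo, frame]`) or without (`[ny, nx, slice, echo]`).
#' @param te_list echo times matching the echo dimension.
#' @param frame_times frame acquisition times, s.
#' @export
as_echo_series <- function(recon, te_list, frame_times = NULL) {
  img <- recon$slice_images
  if (length(dim(img)) == 4) dim(img) <- c(dim(img), 1L)
  # [ny, nx, slice, echo, frame] -> [frame, echo, ny, nx, slice]
  sig <- aperm(img, c(5, 4, 1, 2, 3))
  echo_series(te_list, sig, frame_times)
}

#' Log-linear initialization of the mono-exponential decay fit
#'
#' Ordinary least squares of `log(signal)` on TE: `s0 = exp(intercept)`,
#' `t2s = -1/slope`. Non-positive signals are excluded echo-wise (their
#' logarithm is undefined); with fewer than 2 usable echoes the fit is
#' flagged failed. A non-negative slope (non-decaying data) caps `t2s` at
#' the upper bound with a flag.
#'
#' @param te_list echo times, ms.
#' @param signals magnitude signals, same length.
#' @param t2s_max upper cap for t2s, ms.
#' @return list with `s0`, `t2s`, `ok`, `capped`, `n_used`.
#' @export
loglinear_init <- function(te_list, signals, t2s_max = 2000) {
  use <- which(is.finite(signals) & signals > 0)
  if (length(use) < 2) {
    return(list(s0 = NA_real_, t2s = NA_real_, ok = FALSE, capped = FALSE,
                n_used = length(use)))
  }
  te <- te_list[use]; y <- log(signals[use])
  tb <- mean(te); yb <- mean(y)
  slope <- sum((te - tb) * (y - yb)) / sum((te - tb)^2)
  s0 <- exp(yb - slope * tb)
  if (slope >= 0) {
    return(list(s0 = s0, t2s = t2s_max, ok = TRUE, capped = TRUE,
                n_used = length(use)))
  }
  list(s0 = s0, t2s = -1 / slope, ok = TRUE, capped = FALSE,
       n_used = length(use))
}

#' Mono-exponential T2* fit of one voxel
#'
#' Fits `S(TE) = S0 exp(-TE / T2*)` by Levenberg-Marquardt refinement of
#' the log-linear start (analytic Jacobian, damped normal equations,
#' only cost-decreasing steps are accepted, so the refined residual never
#' exceeds the initializer's). T2* is kept within `bounds` by cap-and-flag
#' rather than failure so that dynamic maps stay dense.
#'
#' @param te_list echo times, ms.
#' @param signals magnitude signals (same length).
#' @param bounds `(lower, upper)` for t2s, ms; default `c(0.1, 2000)`.
#' @param tol convergence tolerance on the cost, default 1e-10.
#' @param max_iter maximum LM iterations (50).
#' @return object of class `relax_fit`: `s0`, `t2s`, `residual` (sum of
#'   squared errors), `converged`, `capped`, `method`, `n_used`.
#' @export
fit_monoexp <- function(te_list, signals, bounds = c(0.1, 2000),
                        tol = 1e-10, max_iter = 50L) {
  init <- loglinear_init(te_list, signals, t2s_max = bounds[2])
  if (!init$ok) {
    return(structure(list(s0 = NA_real_, t2s = NA_real_, residual = NA_real_,
                          converged = FALSE, capped = FALSE,
                          method = "failed", n_used = init$n_used),
                     class = "relax_fit"))
  }
  use <- which(is.finite(signals) & signals > 0)
  te <- te_list[use]; y <- signals[use]

  cost_fn <- function(p) sum((y - p[1] * exp(-te / p[2]))^2)
  p <- c(init$s0, min(max(init$t2s, bounds[1]), bounds[2]))
  cost <- cost_fn(p)
  lam <- 1e-3
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- exp(-te / p[2])
    r <- y - p[1] * e
    j1 <- e
    j2 <- p[1] * te / p[2]^2 * e
    a11 <- sum(j1 * j1); a12 <- sum(j1 * j2); a22 <- sum(j2 * j2)
    g1 <- sum(j1 * r); g2 <- sum(j2 * r)
    improved <- FALSE
    for (try in 1:10) {
      d11 <- a11 * (1 + lam); d22 <- a22 * (1 + lam)
      det <- d11 * d22 - a12^2
      if (abs(det) < .Machine$double.eps * (d11 * d22 + 1)) {
        lam <- lam * 10; next
      }
      dp <- c(d22 * g1 - a12 * g2, d11 * g2 - a12 * g1) / det
      p_new <- p + dp
      p_new[2] <- min(max(p_new[2], bounds[1]), bounds[2])
      cost_new <- cost_fn(p_new)
      if (cost_new <= cost) {
        if (cost - cost_new < tol * (cost + tol)) converged <- TRUE
        p <- p_new; cost <- cost_new; lam <- max(lam / 3, 1e-12)
        improved <- TRUE
        break
      }
      lam <- lam * 10
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  capped <- init$capped || p[2] <= bounds[1] || p[2] >= bounds[2]
  structure(list(s0 = p[1], t2s = p[2], residual = cost,
                 converged = converged, capped = capped,
                 method = "LM-refined", n_used = length(use)),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("<relax_fit> s0 = %.4g, t2s = %.4g ms, SSE = %.3g (%s%s)\n",
              x$s0, x$t2s, x$residual, x$method,
              if (isTRUE(x$capped)) ", capped" else ""))
  invisible(x)
}

# vectorized log-linear fit: S [voxel, echo] with all signals > 0 assumed
# handled by the caller; returns list(s0, t2s (capped at t2s_max), capped)
loglinear_init_mat <- function(te, S, t2s_max = 2000) {
  Y <- log(S)
  tb <- mean(te)
  yb <- rowMeans(Y)
  slope <- (Y %*% (te - tb)) / sum((te - tb)^2)
  slope <- as.vector(slope)
  s0 <- exp(yb - slope * tb)
  capped <- slope >= 0
  t2s <- ifelse(capped, t2s_max, -1 / slope)
  list(s0 = s0, t2s = t2s, capped = capped)
}

# vectorized LM refinement over voxels; S [voxel, echo]
fit_monoexp_mat <- function(te, S, bounds = c(0.1, 2000), tol = 1e-10,
                            max_iter = 50L) {
  init <- loglinear_init_mat(te, S, t2s_max = bounds[2])
  s0 <- init$s0
  t2 <- pmin(pmax(init$t2s, bounds[1]), bounds[2])
  nv <- nrow(S)
  cost <- rowSums((S - s0 * exp(-outer(1 / t2, te)))^2)
  lam <- rep(1e-3, nv)
  active <- rep(TRUE, nv)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    E <- exp(-outer(1 / t2, te))
    R <- S - s0 * E
    J2f <- (s0 * te_outer(te, t2)) * E   # s0 * te / t2^2 * E
    a11 <- rowSums(E * E)
    a12 <- rowSums(E * J2f)
    a22 <- rowSums(J2f * J2f)
    g1 <- rowSums(E * R)
    g2 <- rowSums(J2f * R)
    stepped <- rep(FALSE, nv)
    for (try in 1:8) {
      idx <- active & !stepped
      if (!any(idx)) break
      d11 <- a11 * (1 + lam); d22 <- a22 * (1 + lam)
      det <- d11 * d22 - a12^2
      det[abs(det) < 1e-300] <- NA
      dp1 <- (d22 * g1 - a12 * g2) / det
      dp2 <- (d11 * g2 - a12 * g1) / det
      s0n <- s0 + dp1
      t2n <- pmin(pmax(t2 + dp2, bounds[1]), bounds[2])
      costn <- rowSums((S - s0n * exp(-outer(1 / t2n, te)))^2)
      ok <- idx & is.finite(costn) & costn <= cost
      if (any(ok)) {
        conv <- ok & (cost - costn < tol * (cost + tol))
        s0[ok] <- s0n[ok]; t2[ok] <- t2n[ok]; cost[ok] <- costn[ok]
        lam[ok] <- pmax(lam[ok] / 3, 1e-12)
        stepped[ok] <- TRUE
        active[conv] <- FALSE
      }
      bad <- idx & !ok
      lam[bad] <- lam[bad] * 10
    }
    active[active & !stepped] <- FALSE  # no improving step found
  }
  list(s0 = s0, t2s = t2, residual = cost,
       capped = init$capped | t2 <= bounds[1] | t2 >= bounds[2])
}

te_outer <- function(te, t2) outer(1 / t2^2, te)

#' Voxel-wise dynamic S0 / T2* separation
#'
#' Fits the mono-exponential decay independently for every voxel and frame
#' of a multi-echo series, producing the dynamic TE = 0 extrapolated signal
#' `s0(t)` (T1-dominated) and `t2s(t)` maps. Voxels outside the mask, or
#' with fewer than 2 positive echoes, are `NA`. The fit is deterministic.
#'
#' @param series an [echo_series()].
#' @param mask logical array matching the spatial dimensions (`NULL` = all
#'   voxels with positive first-echo signal in frame 1).
#' @param bounds t2s bounds, ms.
#' @param snr_floor voxels whose mean signal is below `snr_floor` times the
#'   series' robust noise scale are flagged in `low_snr` (fits are still
#'   returned).
#' @return list with arrays `s0`, `t2s`, `residual` (each
#'   `[frame, ...spatial]`), logical `capped`, `low_snr`, and `mask`.
#' @export
fit_volume_dynamic <- function(series, mask = NULL, bounds = c(0.1, 2000),
                               snr_floor = 3) {
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$signals)
  nf <- d[1]; ne <- d[2]; spatial <- d[-(1:2)]
  nv <- prod(spatial)
  sig <- series$signals
  dim(sig) <- c(nf, ne, nv)

  if (is.null(mask)) {
    mask <- array(sig[1, 1, ] > 0, dim = spatial)
  }
  mvec <- as.vector(mask)

  s0 <- array(NA_real_, dim = c(nf, spatial))
  t2s <- array(NA_real_, dim = c(nf, spatial))
  resid <- array(NA_real_, dim = c(nf, spatial))
  capped <- array(FALSE, dim = c(nf, spatial))
  dim(s0) <- c(nf, nv); dim(t2s) <- c(nf, nv)
  dim(resid) <- c(nf, nv); dim(capped) <- c(nf, nv)

  for (fr in seq_len(nf)) {
    S <- t(sig[fr, , ])          # [voxel, echo]
    allpos <- mvec & apply(S > 0, 1, all)
    if (any(allpos)) {
      fit <- fit_monoexp_mat(series$te_list, S[allpos, , drop = FALSE],
                             bounds = bounds)
      s0[fr, allpos] <- fit$s0
      t2s[fr, allpos] <- fit$t2s
      resid[fr, allpos] <- fit$residual
      capped[fr, allpos] <- fit$capped
    }
    # voxels with some non-positive echoes: per-voxel path with exclusion
    partial <- which(mvec & !allpos)
    for (v in partial) {
      f1 <- fit_monoexp(series$te_list, S[v, ], bounds = bounds)
      s0[fr, v] <- f1$s0; t2s[fr, v] <- f1$t2s
      resid[fr, v] <- f1$residual
      capped[fr, v] <- isTRUE(f1$capped)
    }
  }

  msig <- apply(sig, 3, mean)
  noise_scale <- stats::mad(sig[is.finite(sig)], center = 0) / 10
  low_snr <- array(msig < snr_floor * noise_scale & mvec, dim = spatial)

  dim(s0) <- c(nf, spatial); dim(t2s) <- c(nf, spatial)
  dim(resid) <- c(nf, spatial); dim(capped) <- c(nf, spatial)
  list(s0 = s0, t2s = t2s, residual = resid, capped = capped,
       low_snr = low_snr, mask = mask)
}

#' ROI time course of a dynamic map
#'
#' Frame-wise mean and standard deviation of a `[frame, ...spatial]` map
#' over a region of interest.
#'
#' @param map numeric array `[frame, ...spatial]`.
#' @param roi logical array over the spatial dimensions, or integer voxel
#'   indices (into the flattened spatial dimensions). Must be non-empty.
#' @param frame_times optional times, s.
#' @return data.frame with `frame`, `time`, `mean`, `sd`.
#' @export
roi_timecourse <- function(map, roi, frame_times = NULL) {
  d <- dim(map)
  nf <- d[1]
  m <- map
  dim(m) <- c(nf, prod(d[-1]))
  idx <- if (is.logical(roi)) which(as.vector(roi)) else as.integer(roi)
  if (length(idx) == 0) stop("empty ROI")
  sub <- m[, idx, drop = FALSE]
  if (is.null(frame_times)) frame_times <- seq_len(nf) - 1
  data.frame(frame = seq_len(nf), time = frame_times,
             mean = rowMeans(sub),
             sd = apply(sub, 1, stats::sd))
}
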