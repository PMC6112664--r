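#' Contrast-agent bolus model
#'
#' Parameterizes a gadolinium bolus passage as a gamma-variate first pass
#' plus a delayed, dispersed recirculation and a slow approach to a
#' post-bolus steady level. Relaxivities convert concentration to
#' relaxation-rate changes: `1/T1(t) = 1/T1_0 + r1 C(t)` and
#' `1/T2*(t) = 1/T2*_0 + r2s C(t)` (rates in 1/s, concentration in mmol/L).
#' Default relaxivities r1 = 4.0, r2s = 5.0 L mmol^-1 s^-1 are typical
#' gadolinium values at 1.5 T; no published values exist for the emulated
#' acquisition, so they are package defaults, configurable here.
#'
#' @param t0 bolus arrival time, s.
#' @param alpha,beta gamma-variate shape (dimensionless) and scale (s).
#' @param peak_conc first-pass peak concentration, mmol/L. A value of 0
#'   means no injection: all curves are identically zero (including the
#'   steady level, which scales with the bolus).
#' @param r1,r2s longitudinal / effective-transverse relaxivities,
#'   L mmol^-1 s^-1.
#' @param recirculation_fraction fraction of the first-pass peak recirculated
#'   (delayed by `recirc_delay`, dispersed by `recirc_dispersion`), in [0, 1).
#' @param steady_level asymptotic post-bolus concentration, mmol/L.
#' @param recirc_delay,recirc_dispersion,steady_tau recirculation delay (s),
#'   scale multiplier, and steady-state time constant (s).
#' @return object of class `bolus_model`.
#' @export
bolus_model <- function(t0 = 10, alpha = 3, beta = 1.5, peak_conc = 5,
                        r1 = 4.0, r2s = 5.0,
                        recirculation_fraction = 0.15, steady_level = 0.5,
                        recirc_delay = 20, recirc_dispersion = 2,
                        steady_tau = 30) {
  stopifnot(t0 >= 0, alpha > 0, beta > 0, peak_conc >= 0,
            recirculation_fraction >= 0, recirculation_fraction < 1,
            steady_level >= 0)
  structure(as.list(environment()), class = "bolus_model")
}

#' Gamma-variate curve and its closed-form integral
#'
#' `gamma_variate()` evaluates `amplitude * (t - t0)^alpha * exp(-(t - t0)/beta)`
#' for `t > t0` and 0 otherwise. `gamma_variate_integral()` returns its exact
#' integral over `(t0, Inf)`, `amplitude * Gamma(alpha + 1) * beta^(alpha+1)`.
#'
#' @param t time(s), s.
#' @param t0 onset, s.
#' @param alpha,beta shape and scale.
#' @param amplitude multiplier.
#' @export
gamma_variate <- function(t, t0, alpha, beta, amplitude = 1) {
  tau <- t - t0
  out <- numeric(length(t))
  pos <- tau > 0
  out[pos] <- amplitude * tau[pos]^alpha * exp(-tau[pos] / beta)
  out
}

#' @rdname gamma_variate
#' @export
gamma_variate_integral <- function(alpha, beta, amplitude = 1) {
  amplitude * gamma(alpha + 1) * beta^(alpha + 1)
}

#' Compartment concentration curves
#'
#' Evaluates the vascular concentration (peak-normalized gamma-variate first
#' pass + recirculation + steady level) and a tissue concentration obtained
#' by convolving the vascular curve with a single-exponential residue
#' `exp(-tau/tissue_tau)/tissue_tau` scaled by an extraction fraction:
#' the tissue curve is delayed and dispersed relative to the vascular one.
#'
#' @param model a [bolus_model()].
#' @param t_grid strictly increasing times, s.
#' @param tissue_tau tissue residue time constant, s.
#' @param tissue_extraction extraction fraction in (0, 1].
#' @return data.frame with columns `t`, `vascular`, `tissue` (mmol/L).
#' @export
concentration_curve <- function(model, t_grid, tissue_tau = 25,
                                tissue_extraction = 0.35) {
  stopifnot(inherits(model, "bolus_model"), !is.unsorted(t_grid, strictly = TRUE))
  m <- model
  if (m$peak_conc == 0) {
    return(data.frame(t = t_grid, vascular = 0, tissue = 0))
  }
  # peak of tau^a exp(-tau/b) is at tau = a*b, value (a*b)^a exp(-a)
  amp <- m$peak_conc / ((m$alpha * m$beta)^m$alpha * exp(-m$alpha))
  vasc <- gamma_variate(t_grid, m$t0, m$alpha, m$beta, amp)
  if (m$recirculation_fraction > 0) {
    b2 <- m$beta * m$recirc_dispersion
    amp2 <- m$recirculation_fraction * m$peak_conc /
      ((m$alpha * b2)^m$alpha * exp(-m$alpha))
    vasc <- vasc + gamma_variate(t_grid, m$t0 + m$recirc_delay,
                                 m$alpha, b2, amp2)
  }
  tau <- t_grid - m$t0
  vasc <- vasc + m$steady_level * ifelse(tau > 0, 1 - exp(-tau / m$steady_tau), 0)

  # tissue = extraction * (vascular (*) residue), trapezoid quadrature
  n <- length(t_grid)
  tis <- numeric(n)
  for (i in seq_len(n)) {
    tj <- t_grid[seq_len(i)]
    h <- exp(-(t_grid[i] - tj) / tissue_tau) / tissue_tau
    f <- vasc[seq_len(i)] * h
    if (i > 1) tis[i] <- sum(diff(tj) * (f[-1] + f[-i]) / 2)
  }
  data.frame(t = t_grid, vascular = vasc, tissue = tissue_extraction * tis)
}

#' Apply contrast agent to a phantom at one time point
#'
#' Shortens T1 and T2* of every voxel according to its compartment class:
#' vessel voxels see the vascular concentration, tissue voxels the tissue
#' concentration, background (label 0) none. Rates update as
#' `1/T1' = 1/T1 + r1 C / 1000` with T1 in ms and `r1 C` in 1/s.
#' With C = 0 everywhere the volume is returned unchanged.
#'
#' @param volume a `phantom_volume`.
#' @param model a [bolus_model()].
#' @param t time, s (>= 0).
#' @param curves optional precomputed [concentration_curve()] data.frame
#'   containing `t`; computed on a 0.25 s grid up to `t` otherwise.
#' @return a `phantom_volume` with updated `t1`, `t2s`.
#' @export
apply_contrast_agent <- function(volume, model, t, curves = NULL) {
  stopifnot(inherits(volume, "phantom_volume"), t >= 0)
  if (is.null(curves)) {
    grid <- sort(unique(c(seq(0, t, by = 0.25), t)))
    curves <- concentration_curve(model, grid)
  }
  i <- which.min(abs(curves$t - t))
  conc <- c(vessel = curves$vascular[i], tissue = curves$tissue[i])
  if (any(conc < 0)) stop("negative concentration")
  out <- volume
  for (lab in names(volume$classes)) {
    cls <- volume$classes[[lab]]
    cvox <- conc[[cls]]
    if (is.na(cvox) || cvox == 0) next
    sel <- volume$labels == as.integer(lab)
    out$t1[sel] <- 1 / (1 / volume$t1[sel] + model$r1 * cvox / 1000)
    out$t2s[sel] <- 1 / (1 / volume$t2s[sel] + model$r2s * cvox / 1000)
  }
  out
}
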