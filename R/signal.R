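#' Spoiled gradient-echo steady-state signal with T2* decay
#'
#' Signal model for a spoiled gradient-echo (SPGR) acquisition in steady
#' state: the longitudinal (Ernst) term multiplied by mono-exponential
#' transverse decay,
#' \deqn{S = pd \cdot \sin\alpha \frac{1 - E_1}{1 - \cos\alpha \, E_1}
#'          \, e^{-TE/T_2^*}, \qquad E_1 = e^{-TR/T_1}.}
#' At `te = 0` this equals the TE-free base signal S0, the quantity the
#' relaxometry stage extrapolates to.
#'
#' @param pd proton density (arbitrary units, >= 0); may be an array.
#' @param t1 longitudinal relaxation time, ms (> 0); recycled against `pd`.
#' @param t2s effective transverse relaxation time, ms (> 0).
#' @param fa flip angle, degrees, in (0, 90].
#' @param tr repetition time, ms.
#' @param te echo time, ms (>= 0).
#' @return signal in the units of `pd`, same shape as the broadcast inputs.
#' @seealso [ernst_angle()]
#' @export
spgr_signal <- function(pd, t1, t2s, fa, tr, te) {
  stopifnot(all(t1 > 0), all(t2s > 0), fa > 0, fa <= 90, tr > 0, all(te >= 0))
  a <- fa * pi / 180
  e1 <- exp(-tr / t1)
  pd * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-te / t2s)
}

#' Ernst angle
#'
#' The flip angle maximizing the SPGR steady-state signal,
#' `acos(exp(-tr/t1))`, in degrees. For `tr/t1 = 0.3` this is 42.17 deg,
#' rounding to the conventional 42 deg.
#'
#' @param tr repetition time, ms (> 0).
#' @param t1 longitudinal relaxation time, ms (> 0).
#' @return angle in degrees.
#' @export
ernst_angle <- function(tr, t1) {
  stopifnot(tr > 0, t1 > 0)
  acos(exp(-tr / t1)) * 180 / pi
}
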