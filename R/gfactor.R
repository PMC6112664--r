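#' Pseudo-multiple-replica g-factor map
#'
#' Quantifies the spatially varying noise amplification of an SMS
#' reconstruction by the pseudo-multiple-replica method: `n_replicas`
#' independent complex-Gaussian noise instantiations of equal per-sample
#' standard deviation are pushed through (a) the frozen accelerated
#' reconstruction and (b) the single-band reference reconstruction, and
#' the voxel-wise g-factor is the ratio of the resulting per-voxel noise
#' standard deviations, `g(x) = sd_accel(x) / sd_ref(x)`. No `sqrt(R)`
#' factor is applied: the SMS acquisition samples the full k-space of every
#' slice. Voxels with `sd_ref = 0` are flagged undefined (`NA`).
#'
#' Two noise pairings are supported. `paired = FALSE` (default, unbiased):
#' accelerated and reference replicas receive independent noise.
#' `paired = TRUE` emulates calibration schemes in which the accelerated
#' data are synthesized from the same noisy single-band data that form the
#' reference, so both arms share one noise realization per replica; this
#' couples the two variances and biases the ratio (the reason a
#' synthesized-source calibration can report optimistic g-factors).
#' Requires `accel_from_ref`.
#'
#' @param accel_clean noiseless accelerated (collapsed) k-space array.
#' @param ref_clean noiseless reference k-space array (per-slice data).
#' @param recon_accel function(k-space like `accel_clean`) -> magnitude
#'   image array; the frozen SMS reconstruction.
#' @param recon_ref function(k-space like `ref_clean`) -> magnitude image
#'   array of the same shape as `recon_accel`'s output.
#' @param noise_sd per-sample complex noise standard deviation (same for
#'   both arms).
#' @param n_replicas number of replicas (>= 2), default 100.
#' @param seed RNG seed.
#' @param paired share the noise realization between arms (see above).
#' @param accel_from_ref function(noisy ref k-space) -> accelerated k-space;
#'   required when `paired = TRUE`.
#' @param mask optional logical array for the summary statistics.
#' @return list with `gmap`, `mean`, `sd`, `median` (over mask/finite
#'   voxels), `n_undefined`.
#' @export
gfactor_pmr <- function(accel_clean, ref_clean, recon_accel, recon_ref,
                        noise_sd, n_replicas = 100L, seed = 1L,
                        paired = FALSE, accel_from_ref = NULL, mask = NULL) {
  stopifnot(n_replicas >= 2, noise_sd > 0)
  if (paired && is.null(accel_from_ref)) {
    stop("paired = TRUE requires accel_from_ref")
  }
  mean_a <- m2_a <- NULL
  mean_r <- m2_r <- NULL
  with_seed(seed, {
    for (k in seq_len(n_replicas)) {
      ref_noisy <- ref_clean +
        array(complex_noise(length(ref_clean), noise_sd), dim = dim(ref_clean))
      if (paired) {
        accel_noisy <- accel_from_ref(ref_noisy)
      } else {
        accel_noisy <- accel_clean +
          array(complex_noise(length(accel_clean), noise_sd),
                dim = dim(accel_clean))
      }
      ia <- recon_accel(accel_noisy)
      ir <- recon_ref(ref_noisy)
      if (is.null(mean_a)) {
        mean_a <- ia * 0; m2_a <- ia * 0
        mean_r <- ir * 0; m2_r <- ir * 0
      }
      # Welford running moments
      da <- ia - mean_a; mean_a <- mean_a + da / k
      m2_a <- m2_a + da * (ia - mean_a)
      dr <- ir - mean_r; mean_r <- mean_r + dr / k
      m2_r <- m2_r + dr * (ir - mean_r)
    }
  })
  sd_a <- sqrt(m2_a / (n_replicas - 1))
  sd_r <- sqrt(m2_r / (n_replicas - 1))
  gmap <- sd_a / sd_r
  gmap[sd_r == 0] <- NA_real_
  sel <- if (is.null(mask)) is.finite(gmap) else mask & is.finite(gmap)
  list(gmap = gmap, mean = mean(gmap[sel]), sd = stats::sd(gmap[sel]),
       median = stats::median(gmap[sel]), n_undefined = sum(sd_r == 0))
}
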