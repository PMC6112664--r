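---
title: "Models, parameters and design choices in smsepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in smsepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smsepi)
```

# What the package models

Dynamic contrast-enhanced (DCE) perfusion MRI wants two things at once:
T1-weighted signal with a short echo time for leakage quantification, and
T2\*-weighted signal for susceptibility (bolus) contrast — at a temporal
resolution below ~1.5 s and over a large volume. A multi-echo *segmented*
EPI readout delivers several echo times per excitation with a short first
TE; simultaneous-multislice (SMS) excitation recovers the volume coverage
that segmentation costs. `smsepi` simulates that acquisition end to end,
reconstructs the collapsed slice groups with slice-GRAPPA (SG) and split
slice-GRAPPA (SSG) kernels, quantifies the reconstruction, and separates
the multi-echo dynamics into a base signal S0 (TE = 0, T1-dominated) and
T2\*.

## Signal model

Every voxel follows a spoiled gradient-echo steady state with
mono-exponential transverse decay:

$$S(\mathrm{TE}) = \mathrm{pd}\,\sin\alpha\,
\frac{1 - e^{-TR/T_1}}{1 - \cos\alpha \, e^{-TR/T_1}}\; e^{-\mathrm{TE}/T_2^*}
= S_0 \, e^{-\mathrm{TE}/T_2^*}.$$

Assumptions: steady state from the first frame (no transient), perfect
spoiling, ideal box slice profiles, no B0 inhomogeneity beyond the
odd/even readout phase error, no motion, no inflow. The flip angle
maximizing $S_0$ is the Ernst angle $\alpha_E = \arccos(e^{-TR/T_1})$
(`ernst_angle()`); at $TR/T_1 = 0.3$, $\alpha_E \approx 42°$.

## The stated world of the synthetic generator

The phantom is an elliptical body with **T1 = 289 ms** containing five
doped sub-volumes with **T1 = 211 / 434 / 556 / 953 / 1257 ms** (published
values of the physical phantom the package emulates). The remaining
parameters have no published values and are fixed package choices, made
once:

* **T2\***: body 50 ms, sub-volumes 20 / 35 / 50 / 70 / 90 ms, vessel
  100 ms — a plausible spread for doped agar at 1.5 T, wide enough that
  5 ms bins of the contrast-dependency analysis are populated.
* **Proton density**: body 100, sub-volumes 50–170 (a.u.). Doped phantom
  compartments differ in water content; the spread also gives the
  low-flip-angle base signal (which is nearly T1-independent at FA = 5°)
  a multi-bin range, without which an S0-binned analysis is degenerate.
* **Coil maps**: Gaussian magnitude lobes on a ring with smooth linear
  phase, seeded jitter, a per-slice azimuthal twist, and exact
  sum-of-squares normalization. This stands in for a 46-channel array; it
  reproduces the *mechanism* slice unfolding relies on (sensitivity
  variation along PE and slice), not any specific hardware geometry.
* **Noise**: i.i.d. complex Gaussian, identity coil covariance — the
  model under which the pseudo-multiple-replica g-factor is defined.
  n-average ACS data are emulated by dividing the noise SD by sqrt(n).
* **Nyquist ghost**: constant + linear phase (radians, radians/sample)
  applied in hybrid (ky, x) space to odd-polarity readout lines, i.e. to
  lines with odd `floor(ky / n_segments)`; this produces the
  `N_seg`-ghost geometry of segmented EPI and matches what a three-line
  navigator (+, −, + polarity) can estimate.
* **Bolus**: a peak-normalized gamma-variate (arrival 10 s, shape 3,
  scale 1.5 s, peak 5 mmol/L) plus a delayed, dispersed recirculation
  (fraction 0.15) and an exponential approach to a 0.5 mmol/L steady
  level. Tissue sees the vascular curve convolved with an exponential
  residue (25 s) scaled by an extraction fraction (0.35). Relaxivities
  **r1 = 4.0, r2s = 5.0 L mmol⁻¹ s⁻¹** (typical gadolinium values at
  1.5 T) convert concentration to rate changes
  $1/T_1(t) = 1/T_{1,0} + r_1 C(t)$ and likewise for $T_2^*$.

What a green test therefore establishes: the *algorithms* behave as
specified under their own model assumptions. It does not establish
performance on real data — no motion, B1/slice-profile error,
off-resonance distortion, physiological noise, or realistic coil
covariance is simulated, and the published in-vivo error figures
(mean subtraction errors and g-factors of the animal study) are
deliberately **not** reproduced or asserted anywhere.

## Sequence planning

`plan()` assigns ky line `ky` to segment `ky mod n_segments`, giving
`ETL = ceiling(n_pe / n_segments)` lines per segment and echo (17 for
68 lines in 4 segments; with `n_segments` not dividing `n_pe` the last
segment is shorter). Echo-time shifting adds `segment_index * ETS`
(default 150 µs) to each segment's echo times, smoothing the inter-segment
phase staircase. Within one TR all slice groups are excited, so one frame
takes `n_segments` TR periods plus an explicit `dead_time`. The emulated
protocol prints Δt = 1.305 s at TR = 261 ms and 4 segments, which implies
one extra TR-slot per frame; the planner does not hard-code that ratio —
`dead_time = 261` reproduces it. Group ordering is evens-then-odds so
spatially adjacent groups are never excited back to back; with exactly
four groups the plain split would violate that (… 2, 1 …), so that case is
`2, 0, 3, 1`.

## CAIPIRINHA phases

Slice `n` of a group (0-based) is shifted by `n · N_PE / f` pixels along
PE by multiplying its k-space line `ky` with `exp(2πi · ky · n / f)`.
Because a segment's lines are `i, i + n_segments, …`, this per-line factor
is constant over a segment exactly when `f` divides `n_segments · n` —
`validate_shift()` checks this and `caipi_phase()` returns the per-segment
value `2π i n / f (mod 2π)`. The published description of the modulation
factor is typographically corrupted in the source text, so the package
implements this standard linear phase and *validates it against the FFT
shift theorem* (a collapsed noiseless frame equals the sum of reference
slice images circularly shifted by `n·N_PE/f`, up to the deterministic
constant phase `2π·⌊N/2⌋·n/f` that the centered-FFT convention
introduces). Unfolded slices are de-shifted by k-space demodulation with
the conjugate factor — the exact inverse of the collapse, equivalent to
the image-domain circular back-shift plus removal of that constant phase.

Conventions: DC at 0-based index `⌊N/2⌋`, PE along rows, orthonormal
centered FFTs (Parseval holds exactly), 0-based segment/line/group-order
indices in the planner, 1-based slice and group identifiers in R objects.

## Kernel calibration

For target slice $s$ and coil $c$, SG solves the ridge least-squares
problem $\min_K \|T_{s,c} - K \ast S\|^2 + \lambda\|K\|^2$ over all fully
interior ACS positions, where $S$ is the collapsed multi-coil source and
$T$ the CAIPIRINHA-shifted slice target. SSG replaces the single source
with the per-slice sources and drives the response to *other* slices to
zero (leak-block), which is why it cannot be trained from measured,
unseparated SMS ACS data (method 1): it requires the synthesized-source
form (method 2). The two ACS constructions are: method 1 — measured SMS
source + shifted single-band targets, contrasts required to match;
method 2 — source synthesized by collapsing the targets. On noiseless
simulated data both are identical by construction (a regression test
asserts this to 1e-8).

Unpublished numerics, chosen once: kernel footprint **5×5** (ky × kx)
with all coils as sources; ridge **λ = 1e-4, trace-scaled**
(`λ · mean(diag(AᴴA))`); deterministic solve via regularized normal
equations (validated to 1e-8 against an independent dense augmented-QR
solve on small instances). The default ridge trades ~1–3 % signal
shrinkage for noise robustness; noiseless *exactness* tests therefore run
at λ = 0 or 1e-6. ACS echo policies: `acs111` (one kernel from echo 1,
the dynamic-run choice) and `acs123` (per-echo kernels); on matched-
contrast noiseless data they agree to better than 0.01 NRMSE.
Boundary handling is zero padding; the ACS fit uses interior positions
only. 64×64 central-crop ACS downsampling (`downsample_acs()`) preserves
the DC bin exactly.

Navigator correction estimates the odd-line phase from three
non-phase-encoded projections (two positive, one negative polarity): the
linear term from the magnitude-weighted autocorrelation of
`neg · conj(pos)` across readout samples, the constant term from the
residual global phase; both are removed from odd-polarity lines before
unfolding (the default, vendor-style order; a flag reruns with separation
first, for data where ghosting is severe).

## Quality metrics

* **Huang mask**: 256-bin histogram, Huang–Wang membership
  `1/(1+|g−μ_class|/C)` with Shannon fuzzy entropy, minimized over
  thresholds, ties to the lowest threshold; the implementation
  (cumulative sums) is tested against a naive per-threshold sweep.
* **E_diff**: `|(I_SMS − I_SB)/I_SB|` within the mask; zero-reference
  voxels are excluded and counted; scale-invariant by construction.
* **g-factor** (pseudo-multiple-replica, default 100 replicas): per-voxel
  `sd_accel / sd_ref` over independent noise instantiations pushed through
  the frozen reconstructions, no √R factor (SMS samples full k-space per
  slice). A `paired` variant shares one noise realization between the
  arms, emulating calibrations where accelerated and reference images
  derive from identical data; the coupling biases the ratio — on this
  simulation the paired median came out *higher* than the independent one,
  so the package asserts only that the variants differ and reports both.
  A deliberately ill-conditioned case (identical coil maps, no FOV shift,
  near-zero ridge) drives the median masked g above 5, the finite-λ
  shadow of the closed-form divergence for identical sensitivities; at
  the default λ the regularization caps the amplification near that value.
* **Contrast dependency**: low-FA data reconstructed with matched- vs
  mismatched-contrast ACS kernels; ΔS = (S_A − S_B)/S_A binned against
  ground-truth S0 (width 5 signal units) and T2\* (width 5 ms), bins
  anchored at 0, unweighted OLS on bin means (slope `b0`, offset `b1` —
  the field's reporting order). The simulated finding mirrors the source
  study's: fidelity depends on ACS SNR, not on ACS contrast.

## Relaxometry

Per voxel and frame, `log(S)` is regressed on TE (non-positive signals
excluded echo-wise; fewer than two usable echoes flags failure; a
non-negative slope caps T2\* at the upper bound), then refined by a
Levenberg–Marquardt iteration with analytic Jacobian, max 50 iterations,
cost tolerance 1e-10, accepting only cost-decreasing steps — so the
refined residual never exceeds the initializer's. T2\* is bounded to
(0.1, 2000] ms by cap-and-flag so dynamic maps stay dense. Magnitude
(post-SoS) data are fitted directly; the Rician noise floor biases
low-SNR voxels and such voxels (mean signal < 3× a robust noise scale)
are flagged rather than fixed. The volume fitter is a vectorized
re-implementation of the scalar fit and is regression-tested against it;
fits contain no randomness.

## Known limitations

Ideal excitation (no slice-profile or B1 error, no RF hardware effects),
no gradient/eddy-current physics, no motion, no in-plane undersampling or
partial Fourier, Gaussian (not Rician) noise at the simulation stage,
identity coil covariance, and a minimal NIfTI-1 reader/writer that
handles only the package's own uncompressed single-file exports. The
pharmacokinetic interpretation of the separated S0/T2\* curves is out of
scope.
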