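# smsepi

Simulation, reconstruction and quality assessment of
**simultaneous-multislice (SMS), multi-echo, segmented-EPI MRI**, plus the
separation of dynamic contrast-enhanced signals into a T1-dominated base
signal S0 and T2\*.

## The problem

Dynamic contrast-enhanced perfusion MRI needs a temporal resolution below
about 1.5 s to sample the arterial input function, short echo times for
T1-weighted contrast, late echoes for T2\*-weighted contrast, and enough
slices to cover the anatomy. A multi-echo *segmented* EPI readout provides
the echo times; exciting four slices at once (multiband, MB = 4) with
CAIPIRINHA inter-slice shifts of FOV/4 restores the volume coverage. The
collapsed slice groups are then unfolded with k-space convolution kernels —
slice-GRAPPA (SG) or the leak-block variant split slice-GRAPPA (SSG) —
calibrated on autocalibration (ACS) data. Per voxel and time point the
three echoes are fitted to

    S(TE) = S0 * exp(-TE / T2*),        S0 = pd sin(a) (1 - E1) / (1 - cos(a) E1),

with `E1 = exp(-TR/T1)`, giving the dynamic `S0(t)` (contrast-agent uptake
without susceptibility dip) and `T2*(t)` (bolus passage) curves.

`smsepi` is aimed at sequence/reconstruction developers who want a fully
controlled, seeded digital testbed for this acquisition family: every stage
— phantom, coil maps, bolus, k-space encoding with CAIPIRINHA phase
scheduling and Nyquist-ghost injection, navigator phase correction, SG/SSG
calibration and unfolding, Huang-masked subtraction error, pseudo-replica
g-factor maps, contrast-dependency analysis, mono-exponential relaxometry —
is an exported, unit-tested function.

## Worked example

Plan the emulated protocol — 68 phase-encode lines in 4 EPI segments,
24 slices at MB = 4 with a FOV/4 shift, TE = 9/21.5/34 ms, TR = 261 ms,
one dead TR-slot per frame:

```r
library(smsepi)
p <- plan(n_pe = 68, n_segments = 4, n_slices = 24, mb = 4, f = 4,
          te_list = c(9, 21.5, 34), tr = 261, ets = 0.15,
          n_frames = 500, dead_time = 261)
print(p)
#> <sequence_plan>
#>   PE lines        : 68 in 4 segments (ETL = 17)
#>   slices          : 24 (MB = 4, 6 groups, FOV/4 shift)
#>   echoes          : TE = 9 / 21.5 / 34 ms (ETS 0.15 ms/segment)
#>   timing          : TR = 261 ms, dead time 261 ms, dt = 1.305 s
#>   frames          : 500, total 652.5 s (10:52)
#>   group order     : 0 2 4 1 3 5
```

Each segment holds ETL = 17 lines per echo, the temporal resolution is
Δt = 1.305 s, and 500 frames take 10:52 — the protocol's printed values.

Run a small end-to-end pipeline (simulate → calibrate → unfold → QA →
relaxometry) at reduced scale:

```r
cfg <- default_config()
cfg$phantom$grid_shape <- c(2L, 24L, 24L)
cfg$coils$n_coils <- 3L
cfg$acquisition$mb <- 2L
cfg$acquisition$fov_shift_factor <- 2L
cfg$plan$n_frames <- 3L
cfg$qa$g_replicas <- 6L
cfg$log_level <- "quiet"
report <- run_full_pipeline(cfg, tempfile("smsepi"))
print(report)
#> <pipeline_report>
#>   mean E_diff per echo : 0.0158 / 0.0166 / 0.0181
#>   g-factor             : mean 1.166, median 1.022 (sd 0.773)
#>   t2s recovery error   : 0.004 (median relative)
```

Reading: the Huang-masked normalized subtraction error against the
single-band reference is below 2 % per echo (the unfolding is accurate at
this noise level), the median pseudo-replica g-factor is ~1.0 (little
noise amplification for MB = 2 with 3 coils here), and the voxel-wise
T2\* maps recover the programmed phantom values to 0.4 % median relative
error. The output directory also receives HDF5 k-space containers, NIfTI
maps, ROI time-course CSVs and a manifest (config hash, seed, checksums).

A command-line front end with the same stages ships in `inst/cli/smsepi`:

```sh
Rscript inst/cli/smsepi plan
Rscript inst/cli/smsepi pipeline --config my.json --seed 7 --out out/
```

## Documentation

`vignettes/sms-epi-methods.Rmd` describes the models, every tunable
parameter with units and defaults, what the synthetic generator does and
does not emulate, the numerical conventions, and the design choices made
where the published description was silent or ambiguous.
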