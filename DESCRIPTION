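Package: smsepi
Title: Simulation and Reconstruction of Simultaneous-Multislice Multi-Echo Segmented EPI
Version: 0.1.0
Authors@R:
    person("smsepi", "developers", email = "smsepi@example.org", role = c("aut", "cre"))
Description: A simulation, reconstruction and quality-assessment toolkit for
    simultaneous-multislice (SMS) multi-contrast segmented echo-planar MRI.
    Synthesizes multiband, multi-echo, multi-segment k-space acquisitions of
    digital phantoms with CAIPIRINHA phase scheduling, unfolds collapsed slice
    groups with slice-GRAPPA and split-slice-GRAPPA kernels, corrects Nyquist
    ghosts from navigator lines, quantifies reconstruction quality (normalized
    subtraction error with Huang-threshold masking, pseudo-multiple-replica
    g-factor maps, contrast-dependency analysis), and separates dynamic
    contrast-enhanced multi-echo signals into an S0 (T1-dominated) component
    and T2* by voxel-wise mono-exponential fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    rhdf5,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
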