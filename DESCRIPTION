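Package: dihedralCCR
Title: Ramachandran Distributions from Cross-Correlated NMR Spin Relaxation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers residue-level backbone dihedral (Ramachandran)
    distributions of structured and disordered proteins from cross-correlated
    spin-relaxation (CCR) rates. Provides a rigid-backbone forward model of
    CCR structural amplitudes for dipole-dipole, dipole-CSA and CSA-CSA
    interferences, an FFT-based time-correlation-function engine with
    zero-frequency spectral densities, dynamical-proxy deconvolution of
    structure and dynamics, and a regularized maximum-entropy (MAP) inversion
    with Kullback-Leibler prior and L-curve temperature selection. A
    synthetic-ensemble generator with multi-basin dihedral kinetics and
    isotropic tumbling supplies ground-truth data for self-consistent
    validation, mirroring the use of molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'constants.R'
    'fragment.R'
    'rate-registry.R'
    'prefactors.R'
    'surfaces.R'
    'tcf.R'
    'trajectory-vectors.R'
    'rates.R'
    'synthgen.R'
    'maxent.R'
    'gridmetrics.R'
    'io.R'
    'pipeline.R'
    'plot.R'
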