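# dihedralCCR

Residue-level backbone dihedral (Ramachandran) distributions of
structured and disordered proteins, inferred from cross-correlated NMR
spin-relaxation (CCR) rates.

## The problem and who this is for

Intrinsically disordered proteins exist as ensembles of interconverting
conformations, so "the structure" at a residue is a probability
distribution **p**(φ, ψ) over the Ramachandran plane. Remote CCR rates —
interference effects between two relaxation mechanisms (dipole–dipole or
CSA) that share no spin — encode that distribution, but each observable
rate is a convolution of structure and dynamics:

    Γ = A_Γ · τ_Γ

with the structural component A_Γ = Σ p(φ,ψ) · P2(cos θ(φ,ψ)) × physical
prefactors, and the dynamical component τ_Γ the integral of the
normalized time correlation function. This package, aimed at
biomolecular NMR spectroscopists and simulators, implements the full
deconvolution-and-inversion chain:

* a rigid-backbone forward model of amplitude surfaces A_Γ(φ, ψ) for ten
  registered interferences (eight remote rates + two rates with known,
  conformation-independent amplitude) at 800 MHz by default;
* an FFT time-correlation engine (P2 cross-correlations, reversed-order
  averaging, unbiased per-lag normalization, trapezoidal J(0));
* dynamical-proxy deconvolution: correlation times from the two
  known-amplitude rates (nitrogen and carbonyl proxies, two-plane
  averages, optional 0.7/0.3 blend), used to normalize remote rates;
* a maximum-entropy (MAP) inversion of a residue's remote rates into a
  Ramachandran distribution: minimize T·D_KL(p‖q) + χ²/2 on the
  probability simplex, solved deterministically in the 8-dimensional
  dual, with L-curve temperature selection available;
* a synthetic-ensemble generator (multi-basin Markov dihedral dynamics,
  rigid-geometry chain reconstruction, explicit or analytic isotropic
  tumbling) providing ground truth for self-consistent validation;
* grid metrics: 10°×10° histogramming, probability-conserving
  coarsening, and the base-2 Jensen–Shannon divergence in [0, 1].

## A worked example

Forward-generate noisy rates for a residue that is 55% α-helical and 45%
β, then invert them with a broad coil prior:

```r
library(dihedralCCR)

surfaces <- buildRateSurfaces(resolution = 10)
basins <- canonicalBasins(weights = c(0.45, 0, 0.55, 0),
                          spread = c(18, 18, 15, 13))
basins <- basins[basins$weight > 0, ]
truth <- trueBasinGrid(basins, resolution = 10)
obs <- syntheticRates(truth, taus = 3e-9, surfaces, noise = 0.1, seed = 42)
round(rateValues(obs), 2)
#> NHN_CAHA CAHA_NHN1  NHN_NHN1   HAHN1_C     NHN_C  CAHA_Cm1   CAHA_N1     Cm1_C
#>     1.57      4.16      4.82      2.39     -0.57     -2.03      3.33     -7.19
#>    N_NHN     C_CCA
#>     4.44      1.25

prior <- standInCoilPrior(resolution = 10)
problem <- ccrProblem(rateValues(obs)[remoteRateIds()], surfaces,
                      taus = 3e-9, prior, temperature = 1)
fit <- maxentMap(problem)
fit
#> CcrFit: T = 1, chi2 = 0.2986, D_KL = 0.5187 nats, converged (29 evals)

round(basinWeights(posteriorGrid(fit), basins), 3)
#>   beta alphaR
#>  0.469  0.531
jsDivergence(posteriorGrid(fit), truth)
#> [1] 0.05432788
```

The ten rates are a few s⁻¹ at a 3 ns correlation time — the
experimental scale. The inversion recovers the α/β split to three
points (0.531 vs 0.55) and sits at a Jensen–Shannon divergence of 0.054
from the true distribution (0 = identical, 1 = disjoint).

The same machinery runs end to end from trajectories:
`ccrSimulate(spec)` → `ccrRates()` → `ccrInfer()` → `ccrCompare()`; see
the methods vignette (`vignettes/ccr-ramachandran-inference.Rmd`) and
the thin command-line wrapper `inst/scripts/ccr-tool.R` with subcommands
`surfaces`, `simulate`, `rates`, `infer`, `compare`.

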