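---
title: "Inferring Ramachandran distributions from cross-correlated relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Ramachandran distributions from cross-correlated relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dihedralCCR)
```

## The problem

Intrinsically disordered proteins exist as ensembles of interconverting
conformations, so the object of interest at each residue is not a single
(φ, ψ) pair but a probability distribution over the Ramachandran plane.
Cross-correlated spin relaxation (CCR) rates are sensitive reporters of
this distribution: a "remote" CCR rate arises from the interference of
two relaxation mechanisms (dipole–dipole or chemical-shift-anisotropy)
that share no spin, so its amplitude depends on the relative orientation
of interaction vectors on either side of the backbone dihedrals.

Each observable rate is a convolution of structure and dynamics,

$$\Gamma = A_\Gamma \,\tau_\Gamma,$$

where the structural component $A_\Gamma$ is the ensemble average of
$P_2(\cos\theta(\phi,\psi))$ between the two interaction vectors (times
physical prefactors), and the dynamical component $\tau_\Gamma$ is the
integral of the amplitude-normalized time correlation function (TCF). In
a disordered chain $\tau_\Gamma$ varies from site to site, so recovering
$A_\Gamma$ from $\Gamma$ requires an experimentally accessible proxy for
the local correlation time. The package implements the complete chain
from trajectories to distributions:

1. **Forward model** (`buildRateSurfaces`): amplitude surfaces
   $A_\Gamma(\phi, \psi)$ for ten registered interferences — eight remote
   rates plus two rates of known amplitude — on a rigid model backbone
   rotated through φ and ψ in one-degree steps.
2. **TCF engine** (`crossTcf`, `integrateTcf`): zero-frequency spectral
   densities $J(0)$ from vector time series by FFT cross-correlation.
3. **Dynamical proxies** (`proxyTauNNH`, `proxyTauCCCA`): residue-level
   correlation times from the two known-amplitude rates, averaged over
   the two peptide planes that flank a residue.
4. **MaxEnt inversion** (`maxentMap`): the maximum a posteriori
   distribution under a Gaussian likelihood and an entropy prior.
5. **Synthetic ensembles** (`ensembleSpec`, `ccrSimulate`): multi-basin
   dihedral dynamics with known ground truth for self-consistent
   validation.

## The rate model

Three mechanism classes are supported, with prefactors (in SI units,
CSA anisotropies converted from ppm internally):

* dipole/dipole:
  $\frac{2}{5}\left(\frac{\mu_0\hbar}{4\pi}\right)^2
  \gamma_a\gamma_b\gamma_c\gamma_d \, / \, (r_{ab}^3 r_{cd}^3)$,
* dipole/CSA:
  $\frac{4}{15}\frac{\mu_0\hbar}{4\pi}\gamma_a\gamma_b\gamma_u B_0
  \sum_{k=x,y}(\sigma_{kk}-\sigma_{zz}) / r_{ab}^3$,
* CSA/CSA:
  $\frac{8}{45}\gamma_u\gamma_v B_0^2
  \sum_{k,l}(\sigma_{kk}-\sigma_{zz})(\sigma_{ll}-\sigma_{zz})$,

each multiplying the corresponding $J(0)$. Gyromagnetic ratios are
signed ($\gamma_N < 0$), so rates carry physical signs. The carbonyl
tensor defaults to principal values (249.4, 191.1, 87.9) ppm with its xx
axis 37° from the C′–N bond; the amide nitrogen tensor is treated as
effectively axial, stored as differences (170, 0, 0) ppm with the xx
axis 20° from the N–H bond. Storing the nitrogen tensor with
$\sigma_{yy} = \sigma_{zz}$ makes the generic $k = x, y$ sum reduce to
the xx projection automatically, which is exactly how the known
amplitude of the nitrogen proxy rate is defined. Tensor frames are built
per frame: zz is the normal of the plane spanned by the two frame bonds
(C′N/C′O, or N–H/N–C′), and xx is the reference bond rotated by α about
zz.

The ten interferences live in a declarative registry
(`ccrRateKinds()`): each entry names its mechanism class, participating
atoms with residue offsets, and distance mode. All math is driven off
these declarations, so correcting an entry never touches numerical code.
Mean inter-nuclear distances are used everywhere except the non-bonded
Hα(i)–HN(i+1) dipole, whose instantaneous $1/r^3$ travels inside the
correlation function.

### Model backbone

Amplitude surfaces are computed on an otherwise rigid three-residue
backbone fragment with standard internal coordinates (trans ω; N–H =
1.01 Å, Cα–Hα = 1.09 Å; canonical bond lengths and angles), with only
φ and ψ of the central residue variable. All geometry parameters are
overridable through `defaultBackboneGeometry()` or a YAML config, so a
laboratory with refined values can substitute them without code changes.

## TCF estimation choices

`crossTcf` computes $\langle P_2(\mathbf a(0)\cdot\mathbf b(t))\rangle$
via the convolution theorem: the six second-moment component series are
cross-correlated by FFT, summed in the frequency domain, and normalized
per lag by the number of contributing origins (unbiased at every lag —
tails matter because $J(0)$ integrates them). The two series are also
correlated in reversed order and averaged, which symmetrizes the
estimator and improves sampling. $J(0)$ is a trapezoidal integral at the
native frame spacing; exponential fitting is deliberately avoided as
artifact-prone. Default integration bounds are 10 ns (disordered
systems) and 20 ns (slowly tumbling folded proteins), with a convergence
warning when the TCF retains more than 1% of its initial correlation at
the bound.

### Global tumbling: explicit or analytic

The generator can rotate whole frames with an isotropic rotational
random walk (`applyTumbling`; quaternion increments with diffusion
coefficient $D_r = 1/(6\tau_{rot})$, so a body-fixed vector's rank-2 TCF
decays as $e^{-t/\tau_{rot}}$). That path is validated against its
closed forms by Monte-Carlo tests. For quantitative rate work, however,
the package defaults to the standard treatment for rotation-free
trajectories: internal TCFs are multiplied by the analytic factor
$e^{-t/\tau_{rot}}$ (`applyTumblingDecay`) before integration, which is
exact for isotropic tumbling (internal motion and overall rotation are
independent, so the correlation functions factorize) and adds no
sampling noise. The distinction matters: the finite-trajectory noise
floor of an explicitly tumbled TCF tail is of order 0.1 ns in amplitude
units per microsecond of trajectory, which overwhelms small-amplitude
rates — a desk-scale trajectory cannot average it away, while the
analytic factor renders the same computation deterministic.

## Dynamical proxies

The nitrogen and carbonyl proxy rates pair a CSA with a dipole fixed in
the same peptide plane, so their amplitudes are conformation-independent
constants (`knownAmplitudes()`). Dividing the measured rate by the known
amplitude yields a residue-resolved correlation time; the package
averages the rates of the two peptide planes flanking a residue. Each
remote rate is then normalized as $\Gamma / \tau_{proxy}$. Three modes
are available: the carbonyl proxy (default and recommended — the
carbonyl tensor senses multiple spatial directions and is free of the
amide-proton librations), the nitrogen proxy, and a fixed blend
$0.7\,\tau_{C',C'C\alpha} + 0.3\,\tau_{N,NH^N}$ applied only to remote
rates that involve the amide proton. The blend weights are configurable
because their transferability across protein systems is uncertain.
Terminal residues that lack one flanking plane fall back to the single
available plane and are flagged; flagged residues are excluded from
default reporting.

## MaxEnt inversion

With Gaussian uncertainties $\sigma_j$ (set to 1 s$^{-1}$ here) the MAP
estimate minimizes over the probability simplex

$$T\, D_{KL}(\mathbf p \,\|\, \mathbf q) + \tfrac12 \sum_j
\left(\frac{\Gamma_j(\mathbf p) - \Gamma_j}{\sigma_j}\right)^2 ,$$

where $\Gamma_j(\mathbf p) = \tau_j \sum_{\phi\psi} p_{\phi\psi}
A_j(\phi,\psi)$ is linear in $\mathbf p$, $\mathbf q$ is the prior and
$T$ a regularization temperature. Stationarity gives
$p \propto q\,\exp(-\tfrac1T \sum_j \lambda_j \tau_j A_j)$ with
$\lambda_j = (\Gamma_j(\mathbf p) - \Gamma_j)/\sigma_j^2$, so the
problem is solved in the dual: a smooth concave maximization in as many
variables as there are rates (eight), handled by BFGS with analytic
gradient and a damped fixed-point polish. The solver is deterministic
(initialized at $\lambda = 0$, i.e. at the prior), returns feasible
distributions by construction, and — the objective being convex — lands
at the same optimum from any initialization, which the tests verify.
Numerical safeguards: the exponent is shifted by its minimum before
exponentiation; prior bins below a floor of $10^{-12}$ are clamped
before normalization so the KL term stays finite; D$_{KL}$ uses natural
logarithms (the temperature absorbs the base), while the
Jensen–Shannon metric uses base 2 to scale to [0, 1].

Inversion runs at the 1° grid (360 × 360) and results are coarsened to
10° for reporting and comparison. $T$ defaults to 1; `lCurve()` scans
0.01–3 and picks the corner of the (log χ², log D$_{KL}$) curve by
maximum discrete curvature as an automatic substitute for visual
inspection, falling back to $T = 1$ on degenerate curves.

## The synthetic-ensemble generator

The generator stands in for long molecular-dynamics trajectories, which
are not available at desk scale. It emulates the statistical structure
of disordered-backbone dynamics, not molecular mechanics:

* per-residue basin mixtures over the four canonical regions (β at
  (−135, 135), polyproline-II at (−75, 145), α$_R$ at (−63, −43), α$_L$
  at (57, 47)) with wrapped-Gaussian spreads;
* continuous-time Markov exchange between basins (default mean dwell
  5 ns) with the basin redrawn from the stationary weights at each
  event, so the marginal distribution is exactly the analytic mixture;
* intra-basin jitter as an Ornstein–Uhlenbeck process (default
  relaxation 100 ps) with unit stationary variance scaled by the basin
  spread;
* rigid internal geometry (the same internal coordinates as the forward
  model) rebuilt frame by frame along the chain;
* isotropic tumbling, explicit or analytic (default τ_rot 3 ns).

The "true" reference grid is the analytic basin mixture rather than an
empirical histogram, so recovery targets are independent of sampling
noise; the histogram path (`ramachandranHistogram`) exists alongside it.
Defaults are 10⁶ frames at 1 ps. For multi-residue end-to-end runs the
package uses 1 μs of dynamics sampled at 2 ps graining — TCFs with
correlation times ≥ 1 ns are fully resolved at that spacing — and a
10-residue chain, sizes chosen so that validation exercises every code
path at meaningful statistics.

What passing self-consistent tests does **not** show: that real proteins
satisfy the rigid-geometry forward model, that real CSA tensors match
the average values assumed, or that experimental rates reach this noise
level. The validation demonstrates internal consistency of the
inference chain under the generator's assumptions, exactly as a
simulation-based validation against its own reference distributions
would.

## Design choices made where the design was open

* **Registry contents.** The eight remote interferences pair vectors
  across the two peptide planes flanking a residue (sequential amide
  dipoles, amide–αCH dipole pairs, dipole–carbonyl/nitrogen CSA pairs,
  and the sequential carbonyl CSA/CSA interference), the set probed by
  the established backbone CCR experiments; because the registry is
  declarative, substituting a different set is a data edit.
* **Known-amplitude rates and $1/r^3$.** The known amplitudes include
  the mean $1/r^3$ of their dipole, as dimensional consistency with the
  dipole/CSA rate expression requires.
* **Uncertainties.** $\sigma_j = 1$ s$^{-1}$ for all rates; the
  temperature, not the individual σ, is the regularization handle.
* **Grid convention.** Half-open domain [−180°, 180°), bin centers at
  −180 + res/2 + k·res; −180° falls in the first bin and +180° wraps
  onto it. 0·log 0 := 0 in both KL and JS sums.
* **Containers.** Grids, surfaces and rate tables round-trip through
  self-describing plain text ('# key: value' headers over a delimited
  matrix); configuration through YAML with explicit units (MHz, ns,
  degrees at the boundaries; SI internally).

## Known limitations

* The rigid model backbone ignores bond-geometry fluctuations and any
  ω flexibility; glycine/proline and termini get no special treatment
  beyond the terminal single-plane flag.
* Chemical-exchange contributions to measured rates are out of scope.
* One average CSA tensor per nucleus; no residue-type specificity.
* The coil prior shipped here is a synthetic stand-in (a broad
  four-basin mixture); any strictly positive grid can be supplied in
  its place.
* The L-curve corner detector replaces, but does not reproduce, a
  human's visual choice of temperature.

## A worked example

```{r example, eval = FALSE}
spec <- ensembleSpec(basins = variedCanonicalBasins(10, seed = 11),
                     nFrames = 500000L, dt = 2e-12, tauRot = 3e-9,
                     seed = 11)
sim <- ccrSimulate(spec)
rates <- ccrRates(sim$coords, dt = spec@dt, tumblingTau = sim$tumblingTau)
inferred <- ccrInfer(rates)          # 1-degree surfaces, coil prior, T = 1
comparison <- ccrCompare(inferred$fits, sim$truth)
attr(comparison, "meanJS")
```

The same pipeline, at these problem sizes, is what
`scripts/acceptance.R` re-runs from scratch; see the README for the
numbers it produces.
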