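---
title: "Cardiac QTI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac QTI: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioqti)
```

## The signal model and its assumptions

The package treats each imaging voxel as a discrete distribution of
Gaussian diffusion tensors: every component represents a micro-environment
in which diffusion is Gaussian and water does not exchange between
components on the encoding time scale. Under these assumptions a second-order
cumulant expansion of the diffusion-weighted signal in the b-tensor $B$
gives

$$ S(B) \approx S_0 \exp\!\left(-B:\langle D\rangle +
   \tfrac12\, B^{\otimes 2} :: \mathbb{C}\right), $$

with $\langle D\rangle$ the mean diffusion tensor and $\mathbb{C}$ the
fourth-order covariance tensor of the distribution. Three assumptions
matter in practice:

1. **Multi-Gaussianity.** Restricted (time-dependent) diffusion is not
   modeled. The simulator is likewise time-independent, which is a
   deliberate limitation (see below).
2. **Truncation.** The expansion is quadratic in $b$; fitting data at
   large $b \cdot \mathrm{MD}$ produces a systematic truncation bias that
   grows with the third cumulant of the distribution. The validation
   suites therefore operate at $b\cdot\mathrm{MD} \le 0.5$ (property
   tests) and $\le 0.1$ (oracle-equivalence tests).
3. **No exchange, no flow.** Perfusion/IVIM effects are out of scope; an
   acquisition-side mitigation (a nonzero lowest shell) is reflected in
   the default protocol.

Powder-averaging the model over encoding directions at fixed $b$ and
shape $b_\Delta$ yields the scalar form

$$ \bar S(b) \approx S_0\exp\!\left(-b\,\mathrm{MD} + \tfrac16 b^2
   \mathrm{MD}^2\left(\mathrm{MKi} + b_\Delta^2\,\mathrm{MKa}\right)\right), $$

which shows how the isotropic and anisotropic kurtosis enter the $b^2$
term and why at least two distinct $b_\Delta^2$ values are needed to
separate them.

## Metrics

With $M_2 = \mathbb{C} + \langle D\rangle^{\otimes 2}$ (the second moment
of the distribution) and the isotropic projection bases
(`iso_bases()`: bulk $\mathsf{E}_{\mathrm{bulk}}$, shear
$\mathsf{E}_{\mathrm{shear}}$),

- $\mathrm{MD} = \operatorname{tr}\langle D\rangle/3$,
- $\mathrm{FA} = \sqrt{3/2}\,\sqrt{(\langle D\rangle^{\otimes2}:\mathsf{E}_{\mathrm{shear}})/(\langle D\rangle^{\otimes2}:\mathsf{E}_{\mathrm{iso}})}$,
- $\mu\mathrm{FA} = \sqrt{3/2}\,\sqrt{(M_2:\mathsf{E}_{\mathrm{shear}})/(M_2:\mathsf{E}_{\mathrm{shear}} + M_2:\mathsf{E}_{\mathrm{bulk}})}$,
- $\mathrm{MKi} = 3\,(\mathbb{C}:\mathsf{E}_{\mathrm{bulk}})/\mathrm{MD}^2$,
  $\mathrm{MKa} = \tfrac65\,(M_2:\mathsf{E}_{\mathrm{shear}})/\mathrm{MD}^2$,
  $\mathrm{MKt} = \mathrm{MKi} + \mathrm{MKa}$ (an identity, so it closes
  to machine precision on every fit),
- $C_c = \mathrm{FA}^2/\mu\mathrm{FA}^2$, clipped to $[0,1]$ and `NaN`
  when $\mu\mathrm{FA} < 10^{-6}$ (the coherence of an isotropic system is
  undefined).

MKa is normalized by $\mathrm{MD}^2$; an alternative normalization by the
bulk second moment exists in the literature, and keeping the
$\mathrm{MD}^2$ convention makes the MKt identity exact, which the test
suite exploits.

The ground-truth oracle (`ground_truth_metrics()`) computes
$\langle D\rangle$ and $\mathbb{C}$ of a discrete distribution by weighted
sums and derives the metrics through the same code path as the fit, so
"oracle equivalence" compares estimation against exact moments, not two
formula implementations against each other.

## Conventions and units

All user-facing diffusivities are in μm²/ms and b-values in ms/μm², so
$B:D$ is dimensionless; waveform code works in SI and converts when the
b-tensor is formed (1 ms/μm² = 10⁹ s/m²). Voigt vectors carry
$\sqrt2$ on off-diagonal entries so that vector inner products equal
tensor double contractions; this removes all bookkeeping factors from the
design matrix, whose rows are $[1, -\mathrm{v}_6(B), \tfrac12
\mathrm{v}_{21}(B^{\otimes2})]$.

## Fitting choices

- **Covariance fit:** weighted linear least squares on $\ln S$ with
  weights $S^2$ (the first-order variance correction for log-transformed
  data); `"none"` and `"irls"` (three reweighting iterations with fitted
  signals) are available. Nonpositive signals are dropped per voxel; at
  least 28 usable samples spanning two shapes and two shells are required,
  and rank deficiency raises an identifiability error rather than
  returning silent `NA`s.
- **No positivity constraints** are imposed on the fitted covariance;
  slightly negative MKi on noiseless anisotropic data (order $10^{-3}$,
  from truncation) is visible and expected.
- **Powder fit:** Levenberg–Marquardt on $\ln \bar S$ with the analytic
  Jacobian, initialized from a log-linear fit to the two lowest shells.
- **DTI fit:** log-linear start refined by nonlinear least squares in the
  signal domain, restricted to a b-window (default 0.4–0.7 ms/μm²: the
  lower bound suppresses perfusion, the upper bound limits kurtosis bias).

## Waveform analytics

Sample $i$ of a waveform sits at $t_i = (i-1)\,\Delta t$; all time
integrals use the trapezoidal rule on this raster, matching the accuracy
of scanner playback. The refocusing pulse is treated as instantaneous at
the center of the gap, and slice-selection/crusher gradients are not
modeled. Key estimator choices:

- **Spectra.** The encoding power spectrum is $|\mathcal{F}q|^2$ per axis
  with 8× zero padding; the mean frequency is power-weighted over the
  trace spectrum at $f \ge 0$ (including the DC bin, so long
  diffusion-time waveforms score low, as they should).
- **Moment tolerances.** A compensation check passes at order $n$ when
  $|m_k| \le 10^{-4}\,s_k$ for all $k \le n$, where $s_k$ is the
  single-lobe moment magnitude of an uncompensated PGSE of equal b
  occupying the same encoding window ($\delta = T/4$, $\Delta = T/2$). A
  balanced waveform has $m_0 = 0$ exactly, so the *single-lobe* magnitude
  is used as the natural per-order scale; a plain PGSE then passes order 0
  and fails order 1, as it must.
- **LTE-from-PTE labeling.** The planar waveform is decomposed along the
  eigenvectors of the gradient power matrix $\int g\,g^{\mathsf T} dt$.
  Which projection deserves the "long diffusion time" label is genuinely
  ambiguous: the literal largest-eigenvalue rule can select the
  *higher*-frequency component when the in-plane b is balanced, while the
  physical meaning of "long $t_d$" is low spectral content. The default
  (`selection = "spectral"`) labels the lower-mean-frequency projection
  as `lte_long`; the literal gradient-power rule remains available behind
  `selection = "gradient-power"`, and the report carries both eigenvalues
  and both mean frequencies so the choice is auditable.
- **Maxwell index** $\|\int g\,g^{\mathsf T} s(t)\,dt\|_F$ (sign flip at
  the refocusing pulse) is only defined on laboratory-polarity waveforms;
  applying it after the effective-polarity conversion would double-count
  the sign function, so that input is rejected.

## Protocol construction

Directions come from a spherical Fibonacci lattice on the half-sphere —
deterministic, near-uniform (mean outer product within 5% of $I/3$ at
$n = 50$) and reproducible without an optimizer. The acquisition order is
a seeded shuffle followed by a greedy repair pass that forbids consecutive
same-shell entries where possible, which spreads gradient duty cycle
without an unpublished optimizer; the seed permutes only the order, never
the measured multiset. The default design uses shells
$b = [0.1, 0.4, 0.7, 1.1, 1.5]$ ms/μm² with $[10, 20, 30, 40, 50]$
rotations for LTE and PTE (150 samples per shape).

## The simulator: what it emulates, and what it does not

`two_block_phantom()` reproduces a two-block fiber phantom whose mating
blocks rotate from parallel (0°) to perpendicular (90°): slices 1 and 3
are coherent single populations, slice 2 mixes both orientations at equal
weight. Component diffusivities default to $D_\parallel = 2.0$,
$D_\perp = 0.6$ μm²/ms — free-water-scale axial diffusivity at room
temperature for water-filled hollow fibers; the real phantom's compartment
diffusivities are unknown, so only dispersion *properties* (μFA flat, FA
falling, MD constant across angle), never phantom numbers, are asserted.
`dispersion_scenarios()` provides the canonical coherent / dispersed /
crossing / random voxel compositions, and `ventricle_fixture()` a toy
short-axis annulus whose helix angle runs linearly endo→epi (default +60°
to −60°) with sub-voxel orientation aggregation so fitted maps show
μFA > FA.

Simulated signals are exact sums of exponentials (optionally the
truncated-cumulant form, for exact-inversion tests), with seeded Rician
noise $\sqrt{(S+n_1)^2+n_2^2}$, $n_i \sim N(0, S_0/\mathrm{SNR})$.

Deliberately **not** modeled: time-dependent (restricted) diffusion — so
the physical phantom's MD/FA dependence on spectral frequency has no
simulated counterpart — plus exchange, imaging artifacts, and motion.
Passing tests therefore demonstrate estimator correctness under the
multi-Gaussian model, not robustness to every property of real data.

## Validation design and problem sizes

The test suite's problem sizes are chosen so every property is measured
well inside its estimator's resolution:

- Exact inversion: 1000 random tissue-regime coefficient sets on a
  150-entry LTE+PTE design (relative error $<10^{-8}$; observed
  $\sim10^{-15}$).
- Oracle equivalence: 100 random voxel compositions from
  `random_tissue_distribution()` — 2–4 components, $D_\parallel$ 1.0–2.2,
  $D_\perp$ 0.3–1.0 μm²/ms, moderate weights — the myocardial operating
  regime. The exact-mixture branch runs at $b\cdot\mathrm{MD}\le0.1$ with
  16/20/28 rotations per shell: direction sets this dense are needed so
  sampling error does not confound the truncation-control property being
  measured. The 1% agreement premise is a statement about this regime;
  strongly heterogeneous compositions (MKi of order 1) violate it because
  truncation bias scales with the third cumulant.
- Dispersion invariance: interblock angles 0–90° in 10° steps on the
  default design scaled by 0.3 in b (max $b\cdot\mathrm{MD}\approx0.48$).
- Powder/QTI cross-check: orientationally dispersed compositions with 60
  rotations per shell, because the powder model describes rotationally
  averaged signal and sparse powder means leave sampling residuals larger
  than the $b^2$ curvature term.
- Noise robustness: 200 voxels at SNR 50 (seeded), asserting the mean μFA
  bias, not per-voxel precision.

## Known limitations

- Truncation bias at large $b\cdot\mathrm{MD}$ is inherent to the
  quadratic model and is documented, not corrected.
- The arithmetic powder mean over finite rotation sets is an approximation
  to the rotational average; MKi/MKa from the powder route inherit its
  sampling error for coherent anisotropic voxels.
- No outlier rejection, no eddy-current/distortion handling, no restricted
  diffusion: inputs are assumed preprocessed.
- Voxelwise fitting is plain R; grids beyond ~10⁵ voxels will be slow.
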