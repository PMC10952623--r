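# cardioqti

Q-space trajectory imaging (QTI) with tensor-valued diffusion encoding for
cardiac diffusion MRI, in R.

Conventional cardiac DTI summarizes each voxel by a single diffusion
tensor, so it cannot tell a genuine loss of microscopic anisotropy (e.g.
cardiomyocyte disarray) from orientation dispersion of intact, anisotropic
micro-environments (e.g. the transmural helix). Tensor-valued diffusion
encoding probes the voxel with b-tensors **B** of several *shapes* —
linear (LTE, b<sub>Δ</sub> = 1), planar (PTE, b<sub>Δ</sub> = −0.5),
spherical (STE, b<sub>Δ</sub> = 0) — which disentangles the two effects.
This package is aimed at researchers developing or validating such
protocols: it provides the waveform analytics needed to qualify
motion-compensated gradient waveforms for the beating heart, the
covariance-tensor fit and its microstructure metrics, and a multi-Gaussian
phantom simulator with exact ground truth.

## The model

Each voxel is modeled as a distribution of Gaussian diffusion tensors.
A truncated cumulant expansion of the signal gives

```
S(B) ≈ S0 · exp( −B:⟨D⟩ + ½ B⊗B :: C )
```

where ⟨D⟩ is the mean diffusion tensor and C the fourth-order covariance
tensor of the distribution (":" and "::" are double inner products). The
fit is linear in `[ln S0, ⟨D⟩, C]` (28 parameters in Voigt notation) and
requires at least two b-tensor shapes and two shells. From ⟨D⟩ and C the
package derives:

- **MD**, **FA** — mean diffusivity and fractional anisotropy of ⟨D⟩;
- **μFA** — microscopic FA, the anisotropy of the sub-voxel environments,
  insensitive to orientation dispersion;
- **MKi**, **MKa**, **MKt** — isotropic, anisotropic, and total mean
  kurtosis, with MKt = MKi + MKa by construction;
- **C<sub>c</sub>** = FA²/μFA² — orientation coherence (1 = perfectly
  aligned, 0 = fully dispersed).

The powder-averaged (direction-averaged) signal obeys

```
S(b) ≈ S0 · exp( −b·MD + (1/6) b² MD² (MKi + b_Δ² MKa) )
```

which the package fits as an independent route to MD/MKi/MKa.

Waveform analytics cover the dephasing vector q(t) = γ∫g dt, the b-tensor
B = ∫q qᵀ dt, motion-encoding moments m_n = γ∫tⁿ g dt (m₀ = m₁ = m₂ = 0 is
second-order motion compensation), the encoding power spectrum of q(t)
(diffusion-time content), the concomitant-field Maxwell index, hardware
amplitude/slew checks, and the extraction of the two LTE waveforms
embedded in a PTE waveform (long and short diffusion time).

## Worked example

Simulate the two-block fiber phantom (interblock angle 60°), fit the
covariance model per slice, and compare with the simulator's exact ground
truth:

```r
library(cardioqti)

scheme  <- build_protocol(shells = c(0.1, 0.4, 0.7, 1.1, 1.5) * 0.3,
                          rotations = c(10, 20, 30, 40, 50),
                          shapes = c("LTE", "PTE"), seed = 1)
phantom <- two_block_phantom(angle_deg = 60, grid = c(4, 4, 3))
data    <- synthesize_signals(phantom, scheme)

for (z in 1:3) {
  fit <- fit_qti(data$signals[1, 1, z, ], scheme)
  cat(sprintf("slice %d: ", z)); print(metrics_from_coefficients(fit))
}
#> slice 1: MD = 1.067 um^2/ms, FA = 0.644, uFA = 0.644, MKi = 0.000, MKa = 0.459, MKt = 0.459, Cc = 1.000
#> slice 2: MD = 1.067 um^2/ms, FA = 0.464, uFA = 0.643, MKi = -0.001, MKa = 0.457, MKt = 0.457, Cc = 0.520
#> slice 3: MD = 1.067 um^2/ms, FA = 0.644, uFA = 0.644, MKi = 0.000, MKa = 0.459, MKt = 0.459, Cc = 1.000

ground_truth_metrics(phantom$dists[[2]])   # mixed slice, exact
#> MD = 1.067 um^2/ms, FA = 0.464, uFA = 0.644, MKi = -0.000, MKa = 0.459, MKt = 0.459, Cc = 0.518
```

The single-population slices (1, 3) are coherent — FA equals μFA and
C<sub>c</sub> = 1 — while in the mixed slice FA drops with the 60°
crossing but μFA and MD are unchanged: the signature that distinguishes
dispersion from loss of microscopic anisotropy.

Waveform analytics on a PGSE pulse pair (G = 50 mT/m, δ = 10 ms,
Δ = 30 ms):

```r
w   <- make_pgse(G = 0.05, delta = 0.01, Delta = 0.03)
eff <- effective_waveform(w)
btensor_of_waveform(eff)
#> b-tensor: b = 0.4769 ms/um^2, b_delta = 1
#> principal axis: [1.000, 0.000, 0.000]
moments(eff, 3)
#> |m_0| = 2.97e-08 s^0/m
#> |m_1| = 4011 s^1/m
#> |m_2| = 160.5 s^2/m
#> |m_3| = 5.816 s^3/m
```

The b-value matches the closed form γ²G²δ²(Δ − δ/3) ≈ 0.477 ms/μm²; the
nonzero m₁ shows why plain PGSE fails velocity compensation in the moving
heart. For restriction scales, a cardiomyocyte of ~141 μm length and
~19 μm width at MD = 1.6 μm²/ms gives characteristic intermediate
diffusion times of

```r
rt <- restriction_time(c(141, 19), MD = 1.6)
#> 1.55 s (long axis), 28.2 ms (short axis)
```

A command-line front end is provided (`inst/cli/cardioqti`) with
subcommands `protocol`, `simulate`, `fit`, `waveform-info`, and
`repeatability`; each writes a provenance JSON next to its outputs.

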