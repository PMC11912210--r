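---
title: "Parametrizing backbone dihedral potentials against Ramachandran distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametrizing backbone dihedral potentials against Ramachandran distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramaibi)
```

## The problem

Short unfolded peptides — the GxG host–guest systems in particular — sample a
few well-defined basins of the Ramachandran plot (polyproline II, β-strand,
transitional β, helical and turn regions), and spectroscopy (NMR scalar
couplings, vibrational circular dichroism of the amide I′ band) constrains the
mole fractions, positions and widths of those basins.  Classical force fields
often misrepresent these intrinsic propensities.  `ramaibi` implements the
machinery needed to (i) represent binned (φ, ψ) distributions and compare them
quantitatively, (ii) express experiment-derived ensembles as Gaussian
superposition models, (iii) invert a target distribution into a separable
Fourier-series backbone dihedral potential by iterative Boltzmann inversion
(IBI), and (iv) score any candidate ensemble against spectroscopic
observables.

## Distributions and their comparison

The working representation is a probability histogram on a uniform (φ, ψ)
grid.  At the default 2° bin width the bin centers run −179°, −177°, …, 179°
on each axis, 180 × 180 = 32 400 bins.  Binning is half-open (a sample at
angle a belongs to the bin whose center c satisfies c − 1 ≤ a < c + 1) and
+180° wraps onto the −180° side, so every sample lands in exactly one bin.
All constructors normalize to unit mass and every transform preserves that
normalization to 10⁻⁹ or better.

Two distributions are compared with the Hellinger distance in its standard
normalization,

$$H(P,Q) = \sqrt{\tfrac12 \sum_{ij} \left(\sqrt{P_{ij}} - \sqrt{Q_{ij}}\right)^2} \in [0,1],$$

with the conventional four-way similarity banding (very similar up to 0.1,
moderately similar to 0.25, moderately dissimilar to 0.4, very dissimilar
above).  The printed sources for that banding leave the 0.25 boundary
ambiguous (one interval is printed as starting at 0.24); we treat the bands
as contiguous and right-closed.

Mesostate occupancies are probability sums over rectangular regions, with
strict inequalities on bin centers exactly as the region definitions are
printed.  Region free energies are population-weighted means of the per-bin
potential of mean force −k<sub>B</sub>T ln(p/p<sub>ref</sub>) with
p<sub>ref</sub> = 1/(number of bins), so unoccupied regions sit at zero free
energy by convention; no floor is ever substituted into the logarithm.  Note
that the default helical region (ψ up to −14°) and the type I/II′
β<sub>i+2</sub> turn region (ψ from −20°) overlap on a narrow strip; shared
bins are counted in every matching region and the residual `other_fraction`
is measured against the union.

## The Gaussian superposition model

A residue-specific ensemble is modeled as a weighted sum of axis-aligned 2-D
Gaussians, one per mesostate, each with a mole-fraction weight, a center and
per-axis half-widths.  Periodicity is handled by summing images shifted by
±360° in each axis; with half-widths up to 60° the truncation error of the
three-image sum is below 10⁻¹² of the peak.  No φ–ψ correlation term is used
within a component, since only per-axis half-widths are specified by the
models this represents.  Components are normalized individually on the grid,
so the weights remain exact mole fractions regardless of width.  Fitting the
model's parameters to experimental data is out of scope: models are inputs,
and the observables module can score any candidate model.

## Spectroscopic forward models

**J-couplings.**  An observable is predicted as the ensemble average
⟨Q⟩ = Σ q(φ,ψ) p(φ,ψ) over bin centers.  For scalar couplings, q is the
Karplus equation J(θ) = A cos²(θ+θ₀) + B cos(θ+θ₀) + C with the relevant
dihedral (φ, or ψ for ¹J(N,Cα)) and phase tabulated per coupling.  Karplus
coefficients are data, not code: they ship as an editable table
(`inst/extdata/karplus_default.tsv`) holding representative literature-style
values, and any table in the same layout can be substituted.  Because the
integrands are smooth and periodic, the 2° midpoint sum is spectrally
accurate: it agrees with a 0.25° quadrature to well below 10⁻⁴ Hz, which is
the package's accuracy check, not a limit of the method.

**Uncertainties and scoring.**  The total uncertainty of a predicted
coupling combines the experimental error with the reported Karplus-parameter
errors through the pointwise quadrature rule
s̄(θ) = √((s_A cos²)² + (s_B cos)² + s_C² + s_J²), ensemble-averaged over the
distribution; it therefore never falls below the experimental s_J.  For
couplings without published parameter errors (¹J(N,Cα)) the experimental
uncertainty is used alone.  Agreement is summarized by the reduced
χ² = (1/N) Σ ((J_calc − J_exp)/s_i)², reported for all couplings and for the
φ-dependent subset (every shipped coupling except ¹J(N,Cα)).  The N (rather
than N−1) normalization matches the "reduced" labeling of the statistic.

**VCD amide I′.**  The vibrational circular dichroism profile is computed
with a deliberately simple degenerate two-oscillator exciton model: dipole 1
along the laboratory x axis, dipole 2 rotated by φ about z and ψ about y,
separation along z.  This geometry makes the excitonic splitting even and
the rotational strength odd under (φ, ψ) → (−φ, −ψ), so each conformer
contributes a conservative couplet (rotational strengths summing to zero)
and any inversion-symmetric ensemble — the achiral glycine case — gives an
identically zero signal.  All constants (intrinsic wavenumber, splitting
scale, rotational scale, band half-width, Gaussian or Lorentzian shape) are
configurable; the model is an approximation suitable for symmetry and
linearity properties and for relative comparisons, not a quantitative
transition-dipole-coupling parametrization.

## The dihedral potential and its fit

The backbone dihedral potential is separable,
V(φ,ψ) = Σₙ k<sub>nφ</sub>(1 + cos(nφ − γₙ)) + Σₘ k<sub>mψ</sub>(1 + cos(mψ − γₘ)) + offset,
the Amber proper-dihedral form with one term per multiplicity, five terms
per angle by default.  The additive offset is stored (it makes fits exact)
but never exported, being physically irrelevant.

Fitting an energy surface onto this form is linear least squares.  With
fixed phases only cosine terms are fit, which enforces φ → −φ and ψ → −ψ
symmetry — appropriate for achiral (glycine-like) targets.  Chiral targets
need sine content; rather than iterating over a phase grid we fit
a·cos(nθ) + b·sin(nθ), an exact linear reparametrization of k·cos(nθ − γ),
and convert back, canonicalizing to γ ∈ (−90°, 90°] with signed k so that
cosine-only potentials keep signed coefficients with γ = 0.  The loss is the
plain unweighted squared error over unmasked bins by default, with an
optional non-negative weight matrix (see below).

## Iterative Boltzmann inversion

IBI updates the potential by the potential-of-mean-force difference
ΔV = k_BT ln(P_sampled/P_target), fit onto the separable Fourier form, with
k⁽ⁱ⁺¹⁾ = k⁽ⁱ⁾ + λ·Δk.  The initial coefficients are zero.  Convergence is
declared when the Hellinger distance between the sampled and target
distributions falls below a threshold (default 0.01); no stopping rule being
prescribed by the sources, Hellinger is chosen because it is the package's
own comparison metric.  Temperature defaults to 300 K with
k_B = 0.0083144621 kJ/(mol·K); energies are kJ/mol and angles degrees at
every interface (radians internally).

Samplers are pluggable through a one-function contract.  Two are provided:
an exact Boltzmann sampler (the modeled system is a single (φ, ψ) pair, so
the noise-free "simulation" is just exp(−V/k_BT) on the grid) and a
single-chain Metropolis random walk with uniform step proposals, periodic
wrapping, and a histogram of all visited states.  The walk errors out after
10⁴ consecutive rejections rather than spinning.

For exact sampling of an in-span target the scheme converges in a single
step, because ΔV from a flat start *is* the target potential up to a
constant; the parameter-recovery tests exploit this identity.

**Numerical choices for noisy, out-of-span targets.**  Three options exist
because the naive scheme fails in reproducible ways on concentrated targets:

* *Floor handling* (`floor_mode`).  Masking every bin where either
  distribution falls below the floor (the unbiased default, floor 10⁻⁸)
  restricts the fit to the target's support; on a concentrated target the
  restricted trigonometric design becomes nearly collinear and the
  unconstrained extrapolation digs spurious wells.  The `clamp` mode keeps a
  bin whenever either distribution is above the floor and substitutes the
  floor for the other value, preserving a bounded repulsive signal exactly
  where the sampler must be pushed out.  With a histogram sampler the floor
  should sit at the histogram's statistical resolution (a few expected
  counts, e.g. 5/n); a much smaller floor turns zero-count tail bins into a
  persistent attractive bias that pumps coefficients until the loop
  diverges.
* *Loss weighting* (`weighting`).  Weighting the squared error by the
  sampled probability is inverse-variance weighting for log-histogram noise
  (Var ln p̂ ≈ 1/count), and its fixed point is the Kullback–Leibler-optimal
  separable model.  Weighting by sampled + target (`"both"`) additionally
  keeps the target's support in the loss and is the stable choice with
  clamping.
* *Trust control*.  Per-iteration increments are capped at `max_step`
  (20 kJ/mol by default, scaled proportionally), and `run_ibi` restarts from
  the best-scoring potential when an update clearly worsened the fit.
  Neither mechanism activates in the noise-free in-span setting.

The manual-rescaling step used to shrink potential magnitudes after
inversion is exposed as `rescale_potential`, which multiplies all periodic
coefficients by a factor and leaves the offset alone; rescaling by ½ is
exactly equivalent to doubling the temperature of the Boltzmann
distribution.

## Synthetic fixtures: what they emulate and what they do not

`make_target` builds ground-truth ensembles:

* `glycine_like` places components in ±center pairs with equal weights, so
  the distribution is exactly inversion-symmetric — the achiral situation in
  which the VCD signal must vanish identically.
* `alanine_like` contains the two extended basins that dominate alanine
  ensembles in water: pPII at (−66°, 145°) with weight 0.78 and half-widths
  (14°, 12°), and transitional β at (−125°, 145°) with weight 0.22 and
  half-widths (16°, 12°).  Three deliberate design choices: the layout is a
  *product* of a φ-mode and a ψ-mode structure, because a separable
  potential can only generate product distributions and the fixture's
  purpose is to exercise inversion toward an attainable target; the widths
  are at the broad end of spectroscopic basin models, because a five-term
  Fourier series resolves features only down to roughly its 72° highest
  harmonic period and much sharper basins are not representable; and the
  helical band is omitted, because a single 10⁶-step Metropolis walk cannot
  equilibrate exchange across the ~10 k_BT barrier to a separate ψ band, and
  a test fixture must be equilibratable by the sampler that samples it.
  Real alanine ensembles have a few percent helical population and are not
  product-form; passing tests on this fixture demonstrate the machinery, not
  force-field accuracy on real peptides.
* `make_synthetic_experiment` forward-computes noiseless observables and
  adds Gaussian noise with standard deviation equal to the *total*
  per-coupling uncertainty s_i (not the experimental s_J alone): since the
  χ² denominator includes the propagated Karplus-parameter error, only
  noise matched to that denominator calibrates the reduced χ² to 1 in
  expectation, which is what the calibration test asserts.

## Sampling-noise limits of histogram comparison

Two quantitative facts shape what the stochastic tests can assert.  For
i.i.d. sampling from a distribution with B effectively occupied bins,
E[H²] ≈ B/(8n); at n = 10⁶ this gives H ≈ 0.064 for a uniform target on the
full 32 400-bin grid and H ≈ 0.025 for the alanine-like fixture (the latter
verified both by Poisson analysis and by multinomial simulation).  A single
Metropolis chain multiplies H by √τ, where the indicator autocorrelation
τ ≥ (2 − a)/a ≥ 5 at any realistic acceptance rate a simply from rejection
repeats.  The acceptance script measures all three quantities directly: the
i.i.d. floor (≈ 0.025), the Metropolis histogram of the *exactly converged*
potential (≈ 0.073 at step size 90°), and the best Hellinger reached by the
ten-iteration stochastic inversion (≈ 0.075).  The stochastic run therefore
settles at the sampling-noise floor, not at a convergence failure.  Smoothed
comparisons — the Boltzmann distribution of the fitted potential against the
target, ≈ 0.021 here, also reported by the script — are the right metric
when sampling noise must be excluded.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use the full 2° grid for
everything tied to the discretization (parameter recovery over 20 random
potentials, single-step convergence, quadrature comparisons at 0.25°, the
10-iteration Metropolis inversion at 10⁶ steps per iteration, χ² calibration
over 200 synthetic experiments) and a 6° grid for property-style checks
where the discretization is immaterial (metric axioms on random triples,
format round trips).  These sizes were chosen so the whole suite exercises
every code path at the documented defaults.

## Known limitations

* The VCD model is a two-oscillator approximation with configurable
  constants; absolute intensities are not calibrated against experiment.
* Free energies of mesostates depend on the printed region rectangles;
  basins that straddle a region boundary bleed population into
  `other_fraction`.
* The Metropolis sampler is a single chain; multimodal targets with
  well-separated ψ bands need either the exact sampler or externally
  supplied histograms.
* Prime-side dihedral potentials V(φ′, ψ′) are not fit; the exporter can
  only emit explicit zeros for them.
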