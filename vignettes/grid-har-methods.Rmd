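---
title: "Grid-based Hirshfeld atom refinement: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based Hirshfeld atom refinement: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gridhar)
```

## The problem

Conventional X-ray structure refinement (the independent atom model, IAM)
assumes every atom scatters like a spherical, isolated atom. Bonding
density is aspherical — most visibly for hydrogen, whose single electron
sits largely inside the bond — so IAM systematically misplaces H atoms:
refined X–H bonds come out roughly 0.1 Å short of the neutron-diffraction
reference values, and H displacement parameters absorb part of the model
error.

Hirshfeld atom refinement (HAR) replaces the spherical form factors with
aspherical ones obtained by stockholder-partitioning a theoretical electron
density of the actual crystal, and it iterates: refine the geometry against
the data, recompute the density and the partition at the new geometry,
refine again, until the parameters stop moving.

`gridhar` implements the variant of HAR in which the density lives on a
**rectangular periodic grid spanning the whole unit cell** — the natural
representation produced by periodic (plane-wave / real-space)
electronic-structure codes — rather than on atom-centred molecular grids.
The crystal environment is then part of the density by construction; there
is no fragment or cluster-radius choice to make. The package covers the
complete crystallographic side of the method:

1. **Hirshfeld partition.** At each grid point, atom $A$ receives the
   fraction $w_A(\mathbf r) = \rho^{\mathrm{pro}}_A(\mathbf r) / \sum_B
   \rho^{\mathrm{pro}}_B(\mathbf r)$ of the *valence* density, where
   $\rho^{\mathrm{pro}}_A$ is a spherical reference (pro-atom) density
   summed over all periodic images. The frozen-core density never enters
   the weights or the partitioned density; it is assigned completely to
   its atom.
2. **Form factors.** The valence part of each atomic form factor is the
   FFT of the atom's partitioned grid, normalized by $V/N$ and phase
   shifted by $e^{-2\pi i\,\mathbf h\cdot\mathbf x_A}$ to obtain the
   atom-centred value. The core part is computed once per refinement by a
   numerical Fourier–Bessel transform of the spherical core density on an
   exponential radial grid,
   $f(s) = \int 4\pi r^2 \rho(r)\,\mathrm{sinc}(4\pi s r)\,dr$.
3. **Structure factors.** $F_c(\mathbf h) = \sum_j \mathrm{occ}_j\, f_j\,
   T_j\, M_j\, e^{2\pi i\,\mathbf h\cdot\mathbf x_j}$ over the P1
   expansion, with the anisotropic Debye–Waller factor $T = \exp(-2\pi^2
   \sum_{ij} h_i h_j a^*_i a^*_j U^{ij})$ and the optional Gram–Charlier
   multiplier $M = 1 + \frac{(2\pi i)^3}{3!} C^{jkl} h_j h_k h_l +
   \frac{(2\pi i)^4}{4!} D^{jklm} h_j h_k h_l h_m$ for anharmonic motion.
   Symmetry-generated images evaluate the generator's tensors at the
   back-rotated index $R^{\mathsf T}\mathbf h$.
4. **Least squares.** The target is
   $wR_2(F^2) = [\sum w (F_o^2 - k F_c^2)^2 / \sum w F_o^4]^{1/2}$ with
   fixed weights $w = 1/\sigma^2$ (no refinable weighting scheme, so that
   different density models remain comparable). The scale $k$ is
   eliminated by its closed-form minimizer at every function evaluation.
   An optional secondary-extinction parameter $x$ attenuates strong
   reflections via the squared Fc\* convention,
   $F_c^{2,\mathrm{corr}} = F_c^2 [1 + 0.001\,x F_c^2 \lambda^3 /
   \sin 2\theta]^{-1/2}$.
5. **Validation.** Against a neutron reference: signed and absolute X–H
   bond-length differences $\Delta r$; component differences
   $\Delta U_{ij}$ of the H displacement tensors after Blessing scaling
   ($U^{\mathrm x} \approx q\,U^{\mathrm n} + \Delta U$ fitted over the
   non-H atoms in the Cartesian frame); and the ellipsoid similarity
   $S_{12} = 100\,[1 - 2^{3/2}\,(\det U_1^{-1}\det U_2^{-1})^{1/4} /
   \det(U_1^{-1}+U_2^{-1})^{1/2}]$, the percent dissimilarity of the two
   Gaussian probability densities.

## The synthetic density source

A periodic DFT engine is deliberately out of scope; `gridhar` specifies
the density-source contract (valence grid for the cell + per-element core
and pro-atom radial densities) and ships a synthetic implementation so
that every stage is testable end to end:

* `spherical_promolecule` — the valence density is exactly the
  promolecule built from per-element Gaussian-shell mixtures (H: 1
  valence electron; C/N/O: 2 core electrons in the tightest shell, the
  rest valence). The shell widths are documented model constants chosen
  to give densities representable on 0.1–0.2 Å grids; they are **not**
  physical reference data. With this source the Hirshfeld partition
  returns each atom's own pro-atom density and the pipeline reduces
  exactly to an IAM — a strong internal consistency check.
* `aspherical_deformation` — adds, per flagged bond A→B, a dipolar term
  $p\,((\mathbf r-\mathbf x_A)\cdot\hat u)\,e^{-\beta|\mathbf r-\mathbf
  x_A|^2}$ which integrates to zero and shifts atom A's density centroid
  along the bond by the closed-form amount
  $p\,(\pi/\beta)^{3/2}/(2\beta)/n_{\mathrm{val}}$. The defaults $p =
  0.5$ e Å$^{-4}$, $\beta = 4$ Å$^{-2}$ move an H centroid by 0.044 Å —
  the same order as the real bonding-density shift behind the classic
  X-ray H-position bias — while keeping the total density positive.

What the generator emulates: the mechanism by which aspherical bonding
density biases a spherical-model refinement, thermal smearing, counting
noise on $F_o^2$, special positions, and exact scale factors. What it
does not emulate: real wavefunction-level densities, absorption,
anomalous dispersion, thermal diffuse scattering, twinning, disorder, or
resolution-dependent error models. A passing recovery test therefore
demonstrates the correctness of the crystallographic machinery, not the
physical accuracy of any particular density functional.

The simulated data follow $F_o^2 = k\,F_c^2(1 + \eta\xi)$ with standard
normal $\xi$ and $\sigma = k F_c^2 \eta + 0.01\,\mathrm{median}(k F_c^2)$.
The additive floor keeps weights finite for weak reflections; it also
means standardized residuals are mildly deflated for them, which is why
the generator's noise test checks the realized perturbation against its
generating magnitude $k F_c^2 \eta$ rather than against $\sigma$.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| grid spacing | 0.1 | Å | density sampling; the form-factor error is pure aliasing (Poisson summation) and falls off steeply — see the convergence test over 0.2/0.1/0.05 Å |
| interpolation factor | 1 | — | Fourier (zero-padding) interpolation to a finer grid; preserves the integral exactly. Mirrors the wavefunction→density→form-factor spacing ladder (h, h/2, h/4) of grid-based engines |
| radial grid | $2^{13}+1$ points on $[10^{-6}, 30]$ Å | — | exponential grid for core/pro-atom transforms; $2^{19}+1$ is available for production-grade tables but changes results below $10^{-12}$ |
| promolecule image cutoff | $10^{-10}$ | e Å$^{-3}$ | lattice images are summed until the radial density falls below this; the truncation error is orders below the grid discretization error |
| Hirshfeld floor $\varepsilon$ | $10^{-30}$ | (e Å$^{-3}$) | points where the promolecule vanishes contribute to no atom; the density there is numerically zero anyway |
| `shift_tol` | $10^{-6}$ | fractional / Å$^2$ | inner convergence: largest absolute parameter shift of an accepted cycle, the convention of standard refinement programs |
| `har_shift_tol` | $10^{-4}$ | fractional / Å$^2$ | outer (density-update) convergence; below this the form factors no longer change measurably |
| `fsig_cutoff` | 0 | — | optional significance cut on F/σ(F), realized on intensities as $F_o^2/\sigma \ge t^2$ (the mapping from F to F² is convention-dependent; a propagated-error rule is available). Applied once, before refinement |
| extinction | off | — | refined on the intensity scale together with k when enabled |

## Numerical choices

* **Orthogonalization convention**: **a** along Cartesian x, **b** in the
  x–y plane. All Cartesian quantities (U matrices, bond vectors, the
  Blessing fit) use this frame.
* **Fourier convention**: $F(\mathbf h) = \int \rho\, e^{+2\pi i\,\mathbf
  h\cdot\mathbf r}\,dV$; the recentring phase is $e^{-2\pi i\,\mathbf
  h\cdot\mathbf x_A}$, i.e. the established crystallographic phase
  treatment, also when the form factors come from the rectangular grid.
* **Radial quadrature**: composite Simpson in $\log r$ (the exponential
  grid has an odd point count by construction). Trapezoid — the obvious
  first choice — leaves a ~$7\times10^{-7}$ error in the electron count
  that dominates every downstream comparison; Simpson reduces it to
  ~$6\times10^{-13}$. Non-uniform (adapter-supplied) grids fall back to
  trapezoid.
* **Optimizer**: full-matrix damped Gauss–Newton (Levenberg–Marquardt) on
  the analytic Jacobian of the weighted residuals, including the
  closed-form scale's parameter dependence ($\partial r/\partial\theta =
  -\sqrt w\,(k\,\partial I/\partial\theta + I\,\partial k/\partial\theta)$).
  A quasi-Newton (BFGS) line-search implementation was built first; its
  slow creeping tail produces per-cycle shifts below `shift_tol` while
  the parameters are still ~$5\times10^{-4}$ from the optimum, making a
  shift-based convergence criterion unreliable. Gauss–Newton converges
  quadratically on these problems (typically 4–6 cycles), only
  decreasing steps are accepted (the wR2 history is non-increasing by
  construction), and the gradient $2J^{\mathsf T}r$ is validated against
  Richardson-extrapolated central finite differences for every parameter
  class.
* **Special positions** are handled by linear reparameterization, not
  penalties: the site-symmetry group's representation on each parameter
  block (position, $U^{ij}$, $C^{jkl}$, $D^{jklm}$) is group-averaged;
  the average is idempotent, so its column space — extracted by SVD with
  the rank fixed by the trace — is exactly the invariant subspace. Odd-
  rank tensors on an inversion centre get an empty basis and are thereby
  forced to zero; positions are snapped to the exact fixed point before
  refinement (merge tolerance $10^{-6}$ fractional).
* **Floating origin**: in polar space groups (all three directions in P1)
  the intensities are invariant under a common translation. The summed
  positional shift along every polar direction (directions invariant
  under all rotations of the group) is constrained to zero by
  restricting the free parameters to the corresponding null space.
* **Symmetry-equivalent reflections are not merged**; refinement runs
  against the data as given. An optional utility merges with
  inverse-variance weights.
* **Degenerate inputs**: non-positive-semidefinite U during refinement
  warns but does not fail (transient states are legitimate); $S_{12}$
  and the quality report return `NA` for such ellipsoids; an H atom with
  no covalent partner within 1.3 Å is excluded from bond classification
  with a warning; `sin 2θ = 0` reflections skip the extinction term.
* **Quartiles** in the report summaries use the median-unbiased
  convention (R's `type = 8`), with whiskers at 1.5 IQR; box-whisker
  conventions vary enough that this is stated rather than assumed.
* **Hydrogen-bond cutoffs** (H⋯Y < 2.5 Å, X–H⋯Y > 120°, X, Y ∈ {N, O})
  are a configurable convention for the bond-class aggregation, not a
  measurement.

## Problem sizes

The test suite and the acceptance script run on toy cells of 6–10 Å edge
with 2–5 atoms, resolution limits of 0.6–0.8 Å (about 1000–2600
reflections), and grids up to $200^3$ points for the form-factor
convergence study. These sizes were chosen so that every property —
including the full iterative HAR loop — is exercised end to end in a few
minutes on one CPU; nothing in the implementation is specific to them,
and the grid pipeline is $O(N \log N)$ in the number of grid points.

## Known limitations

* No electronic-structure engine is included: the synthetic source stands
  in for it, and external engines connect through the documented
  density-source contract (valence grid + radial core/pro-atom tables).
  Only Γ-point semantics are implemented; Brillouin-zone sampling is an
  engine-side concern acknowledged but not hooked in.
* No estimated standard deviations on refined parameters (the
  Gauss–Newton normal matrix would provide them; listed as an
  extension), no twinning, disorder, anomalous dispersion, absorption,
  restraints, or weighting-scheme refinement.
* Space-group operators must be listed explicitly (CIF xyz strings);
  there is no Hermann–Mauguin/Hall symbol interpreter.
* The CIF reader covers the subset the package writes (cell, symmetry
  loop, atom sites, anisotropic U, Gram–Charlier loops); it is not a
  general CIF parser.
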