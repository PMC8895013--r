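# gridhar — Hirshfeld atom refinement from unit-cell density grids

`gridhar` is an R toolkit for **Hirshfeld atom refinement (HAR)** driven by
periodic electron densities sampled on rectangular grids spanning the whole
unit cell — the representation produced by periodic (plane-wave /
real-space) electronic-structure codes.

Conventional X-ray refinement (the independent atom model, IAM) assumes
spherical atoms, which systematically shortens refined X–H bonds by about
0.1 Å relative to neutron diffraction. HAR replaces the spherical form
factors with aspherical ones obtained by Hirshfeld stockholder
partitioning of a theoretical density, recomputed iteratively as the
geometry refines. In the grid-based variant the partitioned density covers
the complete unit cell, so the crystal environment enters the form factors
by construction and no molecular fragment or cluster radius has to be
chosen.

The package implements the full crystallographic side of the method:

* **Crystal model** — unit cells, metric tensors, explicit symmetry
  operators, P1 expansion with special-position merging, and linear
  reparameterization constraints for atoms on special positions
  (positions, U^ij, Gram–Charlier tensors).
* **Density / partition** — promolecule builder with periodic lattice
  sums, Hirshfeld stockholder partitioning with a frozen-core split
  (the core is excluded from the weights and assigned spherically via a
  Fourier–Bessel transform on an exponential radial grid), FFT-based
  atom-centred valence form factors with the recentring phase shift, and
  Fourier (zero-padding) grid interpolation.
* **Refinement** — structure factors with anisotropic Debye–Waller and
  third/fourth-order Gram–Charlier factors, SHELXL-style secondary
  extinction, the wR2(F²) target with fixed w = 1/σ² and a closed-form
  scale, full-matrix damped Gauss–Newton least squares with analytic
  Jacobians, and the outer HAR iteration
  (density → partition → form factors → least squares → repeat).
* **Validation** — Δr and |Δr| against a neutron reference, ΔU_ij after
  Blessing scaling of the neutron ADPs (q·U + ΔU fitted over non-H
  atoms), the S12 displacement-ellipsoid similarity, hydrogen-bond
  classification (C–H / intra X–H⋯Y / inter X–H⋯Y), and per-class
  summaries.
* **I/O** — CIF subset reader/writer (cell, symmetry xyz loops, atom
  sites, anisotropic U, Gram–Charlier loops), SHELX HKLF4 reflection
  files (bit-exact fixed width), fcf-style reflection output, JSON/CSV
  quality reports.
* **Synthetic density source** — a spherical promolecule source plus a
  bond-directed dipolar deformation with a closed-form centroid shift,
  standing in for an external engine so the whole pipeline runs (and is
  tested) self-contained. External engines plug in through the same
  density-source contract.

## Worked example

Simulate data from an aspherically deformed C–H fragment, then refine them
twice — once with spherical (IAM) form factors, once with the full HAR
loop:

```r
library(gridhar)

st    <- make_toy_structure("diatomic_P1")          # C-H, 1.09 A, P1
bonds <- data.frame(from = "H1", to = "C1")
asrc  <- synthetic_density_source("aspherical_deformation", bonds = bonds)
rs    <- simulate_reflections(st, asrc, d_min = 0.7, noise = 0.01, seed = 1)

ssrc    <- synthetic_density_source("spherical_promolecule")
res_iam <- har_iterate(st, rs, ssrc, refinement_settings(max_har_cycles = 0))
res_har <- har_iterate(st, rs, asrc, refinement_settings(max_har_cycles = 5))

delta_r(res_iam$structure, st, bonds)   # refined vs generating truth
delta_r(res_har$structure, st, bonds)
```

Output (1673 reflections to 0.7 Å, 1% noise):

```
refinement: wR2 = 1.0931%, k = 0.99604, 15 free parameter(s), 5 cycle(s)   # IAM
refinement: wR2 = 1.0074%, k = 1,       15 free parameter(s), 2 cycle(s)   # HAR
IAM  C-H bond: 0.9870 A  (truth 1.0900, bias -0.1030 A)
HAR  C-H bond: 1.0862 A  (truth 1.0900, bias -0.0038 A)
```

The spherical refinement reproduces the classic X-ray artifact — the H
atom is pulled ~0.1 Å along the bond towards the displaced bonding
density — while HAR, refining against form factors partitioned from the
same aspherical density model, recovers the generating position to a few
thousandths of an ångström and fits the data better (lower wR2). The HAR
outer loop converged in 3 density cycles.

A thin command-line front end over the same functions is installed with
the package (`system.file("cli", "gridhar", package = "gridhar")`):

```sh
gridhar simulate --kind diatomic_P1 --dmin 0.6 --noise 0.02 --seed 1 --out sim
gridhar refine   --cif sim.cif --hkl sim.hkl --out iam
gridhar har      --cif sim.cif --hkl sim.hkl --out har
gridhar validate --cif har.cif --ref sim.cif --out report
```

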