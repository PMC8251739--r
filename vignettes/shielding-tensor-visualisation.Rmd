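---
title: "Methods: shielding-tensor decomposition, ring-current models and the Lamb integrator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shielding-tensor decomposition, ring-current models and the Lamb integrator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vistr)
```

## The problem

Aromaticity and antiaromaticity leave a magnetic fingerprint: ring currents
induced by an external field shield or deshield points in and around a
molecule. The standard probe is the nucleus-independent chemical shift
(NICS), the negative isotropic chemical shielding evaluated at a virtual
("ghost", `Bq`) centre — at a ring centre (NICS(0)) or 1–2 Å above the ring
plane (NICS(1), NICS(2)). A single isotropic number, however, hides the
anisotropy that matters most in non-planar and stacked π-systems, where
several ring currents in different planes compete. A striking failure mode:
a stacked antiaromatic dimer can show a near-zero isotropic NICS at its
centre that is actually the average of a strongly positive out-of-plane
component and two strongly negative in-plane components — clear evidence of
through-space currents that the isotropic value erases completely.

`vistr` works with the full 3×3 shielding tensor σ, stored in ppm with the
row index the nuclear-moment component and the column index the field
component (the mixed-second-derivative convention). The package covers the
desk-scale part of the workflow: probe placement, file I/O to and from
quantum-chemistry NMR jobs, principal-axis decomposition, NICS extraction,
and glyph rendering — plus two physics modules (a classical ring-current
simulator and a diamagnetic-shielding integrator) that exercise the whole
pipeline without any quantum-chemistry engine.

## Principal-axis decomposition

The decomposition solves the eigenproblem σ q⁽ⁱ⁾ = t⁽ⁱ⁾ q⁽ⁱ⁾ and visualises
each principal component as a dumb-bell along q⁽ⁱ⁾ with size ∝ |t⁽ⁱ⁾| and
colour by the sign of the NICS contribution −t⁽ⁱ⁾. The isotropic NICS is
−(t⁽¹⁾+t⁽²⁾+t⁽³⁾)/3 = −tr(σ)/3.

A GIAO shielding tensor is in general **non-symmetric**, which raises two
technical points: left and right eigenvectors differ, and a complex
conjugate eigenvalue pair can occur. Two modes are exposed rather than
prescribing one:

* **`symmetrized`** (default): decompose (σ + σᵀ)/2. Eigenvalues are real,
  axes orthogonal. Because the discarded antisymmetric part is traceless,
  isotropic NICS values are bit-identical between modes; only axes and the
  split into components change.
* **`right-eigen`**: right eigenvectors of the raw matrix. When a complex
  pair occurs, the real parts of the eigenvalues are kept, the axes are the
  renormalised real parts of the eigenvectors, `complex_flag` is set, and
  the largest imaginary magnitude is stored in `imag_max`. Nothing is
  silently dropped; renderers draw complex-flagged glyphs semi-transparent.

Deterministic output conventions (needed for byte-stable renders and
regression tests): components are sorted by descending |t| (the "dominant
component" first), ties broken by descending signed value and then by the
axis closest to +z; each axis is sign-fixed so its largest-magnitude
Cartesian entry is positive.

Correctness is checked two ways that never share code with the
implementation: eigenvalues are compared against the roots of the
characteristic polynomial obtained with `polyroot()`, and the eigenvalue
sum is compared with the trace, over large batches of random tensors and
under random rotations (R σ Rᵀ must permute nothing and rotate the axes).

## Probe placement

Ring centres and normals come from the centroid and the best-fit plane of
user-chosen ring atoms; the normal is the direction of least coordinate
variance of the centred atoms, which generalises naturally to puckered
rings, and its sign follows the right-hand rule over the atom ordering.
"Above" the plane means the positive side of that normal; because published
NICS(1) conventions rarely state the side for non-planar systems, mirrored
probes are an explicit `both_sides` option, never an implicit default.
Bond probes displace the bond midpoint along a supplied ring normal; line
scans are endpoint-inclusive with spacing uniform to machine precision;
planar grids support 2D NICS maps. All user-facing coordinates are Å —
conversion to bohr happens only inside the cube reader/writer.

For tilted sub-rings in macrocycles (e.g. phenylenes in a hoop), probe
normals can follow either the local ring plane or the macrocycle plane;
both are constructible from `ring_centroid_normal()` on the respective atom
sets, and the package deliberately does not guess which one an analysis
wants.

## File formats

* **Shielding logs**: the `Magnetic shielding tensor (ppm)` block dialect,
  with labelled `XX=/YX=/ZX=` entries mapped as printed (first letter =
  row). A transposed reading of that convention would change nothing in the
  symmetrized default, and the raw matrix is preserved for right-eigen
  mode. Ghost centres (`Bq`) are flagged; coordinates are taken from the
  input- or standard-orientation block (a parser option, since standard
  orientation may be rotated relative to the input frame).
  `format_shielding_log()` synthesises the same dialect, which gives the
  test suite a full write → parse round trip without a quantum-chemistry
  engine.
* **NMR input decks** list real atoms then ghost centres, with fixed
  6-decimal formatting so output is byte-deterministic.
* **Cube grids** are bohr-convention volumetric files (third index
  fastest); values are written with 7 significant digits so round-trips are
  lossless to better than 1e−6 relative. The negative-atom-count
  molecular-orbital variant is rejected with a clear message rather than
  misread. The bohr→Å constant is fixed at 0.52917721.

## The ring-current simulator (synthetic data)

The generator models an (anti)aromatic ring as a circular loop of radius
*a* whose current responds linearly to the field component along the loop
normal — the minimal model that produces the anisotropy the glyphs are
designed to display. The response strength κ (ppm·Å³) carries all physical
constants, so outputs are directly in ppm and oracle comparisons stay
dimensionless; κ > 0 is diatropic (aromatic), κ < 0 paratropic. Two
evaluators exist:

* the **point-dipole** closed form σ(p) = κ (3 d̂d̂ᵀ − I) n̂n̂ᵀ / |d|³, and
* a **Biot–Savart** discretised wire, normalised so its far-field dipole
  moment equals κ; on the loop axis it reproduces the textbook
  2κ/(a²+z²)^{3/2} profile and it converges to the dipole for |d| ≫ a.

The two implementations are independent of each other and serve as mutual
oracles. The sign structure matches the qualitative NICS phenomenology:
shielded on-axis and deshielded at distant in-plane points for a diatropic
loop, reversed for a paratropic one.

One structural consequence of the normal-only response deserves emphasis:
coplanar ring currents cannot shield in-plane directions, so at the mid-gap
point of a coaxial stack of flat paratropic loops the in-plane NICS
components vanish identically while the out-of-plane component remains
strongly antiaromatic. This is the desk-scale form of the argument that
strong *observed* in-plane shielding between stacked antiaromatic rings
must come from through-space currents: adding an explicit loop whose plane
contains the stacking axis (current up one side, across, down the other)
is what produces the negative in-plane components, and the test suite
demonstrates exactly that contrast.

**Study conditions for the noisy scan** (chosen once, as generator
defaults): a benzene-like loop with *a* = 1.39 Å and κ = 40 ppm·Å³ (giving
an out-of-plane NICS near −16 ppm at 1 Å, a typical aromatic magnitude),
probed at 21 axial points on z ∈ [0.5, 4.5] Å with i.i.d. Gaussian noise of
σ = 0.1 ppm and an explicit seed. `fit_loop()` recovers κ and *a* by
Levenberg–Marquardt least squares on the axial closed form; with these
conditions both parameters come back well within 5 %.

What the generator emulates — and what it does not: it reproduces the
geometry-driven anisotropy, sign structure and superposition of ring-current
fields, which is what the decomposition and rendering layers consume. It
contains no σ-framework density (so no local shielding enhancement inside
bonds), no paramagnetic sum-over-states physics, and no quantitative link
to any DFT ppm value; passing tests therefore validate the pipeline's
mathematics and plumbing, not the ab initio accuracy of any quantum
chemistry.

## The diamagnetic (Lamb) integrator

With the gauge origin fixed at the probe, the diamagnetic shielding is

σ_dia(γβ) = (α²/2) ∫ ρ(r) (r² δ_γβ − r_γ r_β) / r³ dr,

whose diagonal entries are non-negative for any non-negative density and
whose zz component reads the density in the plane perpendicular to z —
the textbook reason in-plane ring currents appear as an out-of-plane
tensor component. The general-component form is the standard tensor
extension of the diagonal formula. α²·10⁶ is fixed at 53.2514 ppm
(α = 1/137.035999). The dia/para split is gauge-dependent; this module
claims nothing beyond the probe-centred convention above, and the
paramagnetic term (which needs excited-state wavefunctions) is out of
scope.

Numerics: midpoint (voxel-centred) quadrature over the cube grid,
accumulated slice-by-slice so memory stays at O(n²) for an n³ grid; voxels
whose centre lies within half a voxel edge of the probe are excluded. The
integrand is O(1/r), so the excluded mass vanishes with resolution —
exclusion is preferred over any smoothing because its error is visible to,
and controlled by, a convergence test. The validation problem is a
normalised spherical Gaussian ρ = (a/π)^{3/2} e^{−ar²}, whose isotropic
diamagnetic shielding has the closed form (α²/3)⟨1/r⟩ with
⟨1/r⟩ = 2√(a/π). The test resolutions — a 12-bohr box at 121³ (0.1 bohr
voxels) against 241³ (0.05 bohr) — were sized so the quadrature error
(empirically O(h²)) sits comfortably inside the 1 % closed-form check while
keeping the whole suite fast; both the relative error and the
halving-change are recomputed, not quoted, by the acceptance script.

## Glyph rendering

A dumb-bell is a capped cylinder with two spherical end lobes. The exact
size mapping is declared, not canonical: length = `scale`·|t| (default
0.04 Å/ppm, capped at 3 Å), lobe radius = 0.25 × half-length, cylinder
radius = 0.4 × lobe radius, display threshold 1 ppm — defaults chosen so a
typical aromatic NICS(1) tensor renders about 1.2 Å long, and all of them
are arguments, not constants. The colour rule is total: blue iff the NICS
contribution is negative (shielded/aromatic), red otherwise. Backends: a
self-contained VMD draw script (TCL), a triangulated OBJ mesh (cylinder
shell + two UV spheres per glyph, resolution parameters exposed), a
lossless JSON scene record, and a quick-look ggplot2 projection. All text
output uses fixed 6-decimal coordinates and LF endings, so identical scenes
produce identical bytes.

## Degenerate and edge inputs

* Eigenvalue ties (e.g. the two in-plane components of a symmetric ring):
  ordering falls back to signed value, then axis-closest-to-+z, so output
  is reproducible; tests treat the degenerate subspace as a subspace rather
  than pinning individual axes.
* Collinear "rings" have no plane and raise a geometry error; probes
  coincident with an atom trigger a warning (the local density dominates
  there), not a failure.
* The dipole evaluator is singular at the loop centre and the Biot–Savart
  evaluator on the wire; both raise errors naming the offending loop/probe
  pair rather than returning large numbers.
* Negative densities are rejected by the Lamb integrator (electron
  densities cannot be negative; a signed field indicates a difference or
  orbital cube, which the integral is not defined for).

## Problem sizes used by the checks

Batch sizes were fixed once for the test suite and acceptance script:
1000 random tensors for the trace/oracle identities, 200 random rotations
for equivariance, 512 wire segments for the Biot–Savart reference, the
121³/241³ Gaussian grids above, and the 21-point noisy scan. The
acceptance script (`scripts/acceptance.R`) recomputes every reported
quantity from scratch at these sizes under a caller-supplied seed.

## Known limitations

* No quantum chemistry: tensors are parsed or simulated, never computed
  from wavefunctions; quantitative DFT NICS values are outside what the
  classical loop model can or should reproduce.
* One log dialect is parsed natively; other engines enter via the CSV/JSON
  tensor-table interface.
* No automatic ring perception — ring atom indices are user input.
* The right-eigen mode reports real parts of complex pairs with a flag;
  a full complex visual encoding (beyond transparency) is not attempted.
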