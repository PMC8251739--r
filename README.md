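# vistr — visualisation and analysis of chemical shielding tensors

`vistr` is an R toolkit for tensor-resolved aromaticity analysis. The
nucleus-independent chemical shift (NICS) — the negative isotropic chemical
shielding at a virtual point, NICS = −σ_iso = −(σ_xx + σ_yy + σ_zz)/3 — is
the standard magnetic criterion for aromaticity (negative = aromatic,
positive = antiaromatic), but a single isotropic number hides the
anisotropy that dominates non-planar macrocycles and stacked π-systems.
`vistr` instead decomposes the full 3×3 shielding tensor σ into its
principal axes q⁽ⁱ⁾ and eigenvalues t⁽ⁱ⁾,

    σ q⁽ⁱ⁾ = t⁽ⁱ⁾ q⁽ⁱ⁾,  i = 1, 2, 3,    NICS = −(t⁽¹⁾ + t⁽²⁾ + t⁽³⁾)/3,

and renders each component as an oriented dumb-bell glyph whose length
tracks |t⁽ⁱ⁾| and whose colour encodes the sign of the NICS contribution
−t⁽ⁱ⁾ (blue = shielded/aromatic, red = deshielded/antiaromatic). Because
GIAO shielding tensors are generally non-symmetric, both a symmetrized
decomposition (real eigenvalues, orthogonal axes; the default) and a
right-eigenvector decomposition of the raw matrix (with explicit flagging
of complex conjugate pairs) are provided.

The package is aimed at computational chemists who already run NMR/NICS
jobs in a quantum-chemistry engine and want the surrounding tooling in R:

* **probes** — ghost-atom (`Bq`) probe generation: ring centroids and
  best-fit-plane normals, NICS(0)/NICS(1)/NICS(2) offsets, bond probes,
  line scans, planar grids; XYZ I/O.
* **tensor core** — tensor tables (tidy tibbles, one probe per row),
  symmetrization, principal-axis decomposition, isotropic and directional
  NICS; broom-style `tidy()`/`glance()` methods.
* **qc I/O** — parsing of `Magnetic shielding tensor (ppm)` log blocks,
  ghost-atom NMR input decks, cube-format density grids, CSV/JSON tensor
  tables.
* **ring-current simulator** — classical diatropic/paratropic current
  loops (point-dipole and Biot–Savart evaluators), field superposition,
  noisy scan generation and loop-parameter fitting: a physics oracle that
  exercises the full pipeline with no quantum chemistry.
* **Lamb integrator** — numerical diamagnetic shielding tensor
  σ_dia = (α²/2)∫ρ(r)(r²δ − r rᵀ)/r³ dr from a cube density, gauge origin
  at the probe.
* **rendering** — VMD draw scripts (TCL), OBJ meshes, lossless JSON
  scenes, ggplot2 projections; byte-deterministic output.
* **CLI** — `vist_cli()` plus the thin `inst/cli/vist.R` wrapper with
  `probe`, `analyze`, `render`, `simulate` and `lamb` subcommands.

## Worked example

The classic benchmark: at the centre of an aromatic ring the decomposition
shows a dominant out-of-plane shielding component and two smaller in-plane
ones. Feeding the printed benzene NICS(0) principal shieldings
(13.3, 6.7, 6.7 ppm) through the decomposition:

```r
library(vistr)
vist(diag(c(13.3, 6.7, 6.7)), label = "benzene NICS(0)")
#> <vist> benzene NICS(0)  mode=symmetrized
#>   isotropic NICS: -8.9000 ppm
#>   t(1) =   13.3000 ppm  (NICS  -13.3000)  axis [ 1.0000  0.0000  0.0000]
#>   t(2) =    6.7000 ppm  (NICS   -6.7000)  axis [ 0.0000  0.0000  1.0000]
#>   t(3) =    6.7000 ppm  (NICS   -6.7000)  axis [ 0.0000  1.0000  0.0000]
```

The dominant component contributes −13.3 ppm of shielding and the three
components average to the isotropic NICS(0) of −8.9 ppm.

The same pipeline end to end on synthetic data — place probes above a
benzene-like ring, evaluate a diatropic ring-current loop there, decompose
and build glyphs:

```r
mol    <- benzene_geometry()
ring   <- ring_centroid_normal(mol, 1:6)
probes <- ring_probes(ring$centre, ring$normal, offsets = c(1, 2), prefix = "NICS")
decomp <- current_loop(radius = 1.39, strength = 40) |>
  field_scan(probes, method = "biot-savart") |>
  vist_decompose()
decomp[, c("label", "component", "t", "nics", "axis_z", "nics_iso")]
#> # A tibble: 6 × 6
#>   label      component     t   nics axis_z nics_iso
#>   <chr>          <int> <dbl>  <dbl>  <dbl>    <dbl>
#> 1 NICS_+1.00         1 15.9  -15.9       1    -5.31
#> 2 NICS_+1.00         2  0      0         0    -5.31
#> 3 NICS_+1.00         3  0      0         0    -5.31
#> 4 NICS_+2.00         1  5.54  -5.54      1    -1.85
#> 5 NICS_+2.00         2  0      0         0    -1.85
#> 6 NICS_+2.00         3  0      0         0    -1.85

build_glyphs(decomp)[, c("label", "nics", "length", "colour")]
#> # A tibble: 2 × 4
#>   label        nics length colour
#>   <chr>       <dbl>  <dbl> <chr>
#> 1 NICS_+1.00 -15.9   0.637 shielded-blue
#> 2 NICS_+2.00  -5.54  0.221 shielded-blue
```

Above the ring the loop shields only along its normal (negative NICS
component along z, blue glyph), decaying with distance — the signature of a
diatropic ring current. `vist_scene()` + `render_tcl()`/`export_scene()`
turn the glyph table into VMD, OBJ or JSON scenes, and
`plot_vist_scene()`/`plot_nics_scan()` give quick ggplot2 views.

The same steps from a shell:

```sh
Rscript inst/cli/vist.R probe --xyz benzene.xyz --ring 1,2,3,4,5,6 \
    --offsets 0,1,2 --out probes.csv --deck job.gjf
Rscript inst/cli/vist.R analyze --input job.log --out decomp.csv
Rscript inst/cli/vist.R render --input decomp.csv --format tcl --out scene.tcl
```

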