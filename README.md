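# trapmorph

Growth models and morphometrics for the development of *Utricularia gibba*
suction traps.

The trap is an epiascidiate (cup-shaped) leaf: between roughly 4 and 10.5
days after initiation (DAI) it transforms from a near-spherical shell about
100 µm across into an oblate spheroid with a straightened, extended ventral
midline. `trapmorph` implements the growing-polarised-tissue account of that
transformation and the quantitative analyses used to test it, so that the
tissue-level, cellular, clonal, staging, and gland-polarity results can all
be reproduced and probed on synthetic inputs.

## The model

The tissue is a **canvas**: a closed triangulated sheet with wall thickness,
carrying regional factors fixed to the material — MID on the sagittal
midline, STK at the stalk pole, VEN on the ventral midline arc, and a mouth
region. A diffusible **polariser (POL)** is produced where STK is high
(+organiser) and degraded at the mouth (−organiser); its frozen gradient
defines a stalk-to-mouth polarity field. A growth regulatory network (KRN)
then sets the *specified* growth-rate tensor per element:

- `K_par`, `K_per` — rates parallel and perpendicular to the local polarity
  (h⁻¹), `K_nor` — rate in thickness;
- promotion and inhibition act multiplicatively:
  `pro(z, i) = 1 + z·i`, `inh(z, i) = 1 / (1 + z·i)`;
- e.g. the areal-conflict model: `K_par = K_per =
  b_planar · pro(p_mid, i_mid) · inh(h_stk, i_stk) · pro(p_ven, i_ven)`,
  with `b_planar = 0.0145 h⁻¹`, and the directional-conflict models keep
  `K_par + K_per = 2·b_planar` so only orientations differ.

*Resultant* growth — what each region actually does under mechanical
connectivity — is obtained by minimising the residual elastic strain energy
between the deformation and the specified per-element stretch
`exp(K·dt)` on a single layer of wedge (prism) elements spanning the wall,
with residual strain fully dissipated after each step (plastic growth).
Emergent curvature is how areal conflicts (nonuniform rates) and directional
conflicts (nonuniform orientations of anisotropy) are resolved.

On top of the tissue model:

- **virtual cells** tile the outer surface (spherical centroidal Voronoi),
  ride with the growth, and divide when they reach the threshold area
  `T_A = 70 µm²` while competence (CDIV) lasts (until 6.5 DAI, never in the
  stalk); clones are induced by marking ~40 % of cells;
- **morphometrics**: exponential strain-rate fits of log length vs time,
  developmental staging `DAI = ln(L/10 µm) / (0.018 h⁻¹ · 24)` (with a
  5.78 % shrinkage correction for fixed specimens), section circumference
  extraction, second-moment cell anisotropy `a = (r − 1)/(r + 1)` with
  `r = √(λ₁/λ₂)`, and the clone / cell-number / cell-shape anisotropy
  decomposition;
- **quadrifid gland polarity**: from five 3-D landmarks per gland, arm pairs
  are found from the six centre-subtended angles, and a polarity is assigned
  towards the more widely splayed pair when the tip distances differ by at
  least 2 µm (DistArms), optionally requiring agreement with the arm-length
  criterion (SumArms);
- **synthetic generators** for growth series, gland landmark fields and
  labelled cell mosaics with known ground truth.

## Worked example

```r
library(trapmorph)

# Stage traps from their length: a 139 um live trap, and a 899 um
# OPT-imaged (fixed, shrinkage-corrected) mature trap
round(stage_from_length(139), 1)                  # 6.1  (DAI)
round(stage_from_length(899, fixed = TRUE), 1)    # 10.5 (DAI)

# Run the integrated areal+directional model from 4 to 10.5 DAI
# (reduced resolution for a quick run; drop the overrides for full scale)
res <- run_preset("fig6MP",
                  overrides = list(canvas = list(subdivision_level = 3),
                                   dt = 2), seed = 1)
round(res$measurements$circumference)
#>   sagittal    frontal transverse
#>       4225       2654       3221
m <- trap_midline_metrics(res$trajectory)
signif(c(m$sagittal_rate, m$ventral_rate, m$ventral_straightness), 3)
#> 0.0167 0.0171 0.1050
```

The sagittal circumference ends up the longest of the three — the sphere has
flattened into an oblate spheroid — and the ventral midline grew fastest
(0.0171 h⁻¹) while staying relatively straight (chord deviation ~11 % of
chord length; the pure areal-conflict model gives ~15-25 % — a bulge).

```r
# Score a synthetic quadrifid gland field with 20 degrees of angular noise
qf <- gen_quadrifid_field(n = 40, splay_diff = 6, angular_noise = 20, seed = 2)
glands <- lapply(qf$glands, assign_polarity)
summarize_field(glands, qf$stalk_point, qf$mouth_point)$counts
#>      aligned anti_aligned   unassigned        total
#>           40            0            0           40
```

All 40 gland polarities point from stalk to mouth, the signature of a
coherent proximodistal polarity field.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch and at the published scale
(~5120-triangle canvas, 1 h steps, 4→10.5 DAI): the resultant areal strain
rate of the stalk region in the areal-conflict model, the resultant stalk
strain rate parallel to the polarity in the directional-conflict model, and
the second-moment anisotropy of a 2:1 cell. Run it from the repository root
against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

- `R/canvas.R`, `R/krn.R`, `R/solver.R` — canvas construction, growth
  regulatory networks, and the growth solver;
- `R/cells.R`, `R/morphometrics.R`, `R/quadrifid.R` — virtual cells and
  divisions, shape/strain/clone measurements, gland polarity;
- `R/synthetic.R` — ground-truth generators; `R/interface.R` — presets and
  configuration; `R/io.R` — VTK/PLY/OBJ/CSV export;
- `vignettes/trap-growth-methods.Rmd` — the methods notes: model
  assumptions, parameter choices, numerical decisions, and known
  limitations (including where this solver's conflict resolution differs
  quantitatively from the original MATLAB framework).
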