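# protonarc

Desk-scale automated treatment planning for intensity-modulated proton
therapy (IMPT) and discrete proton arc therapy (PAT) on synthetic
phantoms, with one shared optimizer across delivery approaches so that
their comparison is free of planning bias.

Head-and-neck proton plans are built from thousands of candidate pencil
beams ("spots", indexed by field, energy layer and lateral position).
Delivering an arc from 36 directions improves organ-at-risk sparing but
multiplies the number of energy layers (ELs) — and EL switches dominate
delivery time. This package implements the planning stack that makes the
trade explicit and comparable:

* **Wish-list driven lexicographic MCO** — hard constraints (robust
  target min/max dose over 21 setup/range error scenarios, a 47 Gy
  per-field dose cap) plus strictly prioritized objectives, solved one
  priority at a time under epsilon-constraints on the higher priorities.
  Each stage is a ridge-regularized QP with cutting planes for the
  voxel-wise constraints; the result is Pareto-optimal in the spot
  weights on its support.
* **SISS** — sparsity-induced spot selection: an L1 penalty
  `c · Σ w_j` on the scalarized wish-list surrogate picks the
  high-weight spot support before MCO.
* **ELR** — energy-layer reduction for PAT: a group lasso
  `λ Σ_g √|g| ‖w_g‖₂` over (field, energy-layer) groups sparsifies the
  EL space; λ trades EL count against plan quality, and `tune_lambda()`
  bisects to a target count. λ = 0 is the 36-field "Utopia" benchmark
  (no reduction, best attainable dosimetry).
* **BAO** — patient-tailored beam-angle selection: the same group
  machinery with one group per beam over 72 equiangular candidates;
  the N highest-norm beams form the personalized configuration, planned
  with and without range shifters (34 mm WET) keeping the better plan.
* **Finalization** — minimum/maximum monitor-unit enforcement with one
  constraint-restoring re-solve, then normalization so that CTV70 D98%
  of the 21-scenario voxel-wise minimum dose equals 95% of the 70 Gy
  prescription.
* **Evaluation** — DVH metrics (Dmean, D98% of VWmin, D2% of VWmax),
  logistic NTCP models (illustrative coefficients shipped as config),
  integral dose, and exact paired two-sided Wilcoxon signed-rank tests
  between planning modes.

Dose comes from a simplified analytic pencil-beam engine (parametric
Bragg curve, depth-growing Gaussian penumbra, ray-marched radiological
depth) on synthetic oropharynx-like phantoms — the algorithms are the
point, not clinical dosimetry.

## Worked example

```r
library(protonarc)

phantom <- generate_phantom(default_phantom_spec(), seed = 1)
res <- run_mode(phantom, "cs4", pa_config())   # 4-field class solution,
print(res$plan)                                # 21-scenario robust MCO
```

```
<protonarc_plan> mode cs4: 4 fields, 113 spots (91 active), 56 ELs
  priority   structure    metric goal robust  achieved
1        1   parotid_l mean_dose   10  FALSE  4.867442
2        2   parotid_r mean_dose   10  FALSE  1.271500
3        3 constrictor mean_dose   24  FALSE 51.194442
4        4        cord  max_dose   32  FALSE 41.560215
5        5        body mean_dose    4  FALSE 23.481466
```

The achieved column is read against the wish-list: the parotid mean
doses (priorities 1–2) beat their 10 Gy goals; the constrictor —
wrapped around the high-dose target on this phantom — cannot reach its
goal and absorbs what the higher priorities leave; the cord maximum
stays under its 45 Gy hard constraint. Evaluation
(`print(res$report)`) adds DVH metrics per structure, NTCP values,
and the plan summary:

```
  mode integral_dose_gy_l n_spots n_els total_mu summed_ntcp_g2 summed_ntcp_g3
1  cs4              1.647      91    56     2365         0.8423         0.3578
```

with CTV70 `d98_vwmin_gy = 66.50` — exactly 95% of the 70 Gy
prescription after normalization — and every field's maximum dose
contribution at or below the 47 Gy cap
(`per_field_max_dose(res$plan, res$dij, f)`).

A population comparison mirrors the cohort design: seeded phantoms,
every mode under one wish-list digest, paired exact statistics:

```r
study <- run_study(seeds = 1:10, modes = c("cs4", "utopia36"),
                   config = pa_config())
study$comparisons   # per-metric median difference + exact Wilcoxon p
```

A thin CLI wraps the same functions:
`Rscript inst/cli/protonarc.R phantom --out ph/ --seed 1`, then
`plan --phantom ph/ --mode cs4 --out plan/`, `study`, `evaluate`, …

## Layout

| Path | Contents |
| --- | --- |
| `R/phantom.R`, `R/nrrd.R` | synthetic phantoms, NRRD raster I/O |
| `R/beamline.R` | beam sets, spots, blocking, pencil-beam dose engine |
| `R/scenarios.R` | 21-scenario robustness set, voxel-wise aggregates |
| `R/wishlist.R`, `R/mco.R`, `R/solver.R` | wish-lists, lexicographic MCO, QP/cutting-plane/MM core |
| `R/siss.R`, `R/elr.R`, `R/bao.R` | the three sparsification stages |
| `R/finalize.R`, `R/evaluate.R` | MU limits, normalization, DVH/NTCP/statistics |
| `R/pipeline.R`, `inst/cli/protonarc.R` | mode orchestration, studies, CLI |
| `R/fixtures.R` | toy problems with brute-force oracles |
| `vignettes/planning-methods.Rmd` | models, assumptions, numerical choices |
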