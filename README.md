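# dsbfoci

Automated quantification of DNA double-strand-break (DSB) repair foci —
γH2AX and 53BP1 — in three-dimensional multi-channel fluorescence image
stacks, with cell-cycle stratification by EdU image cytometry.

DSBs are visualised as bright nuclear foci; their number per nucleus
measures DNA damage, and its decline after irradiation measures repair.
Because S/G2 cells carry far more spontaneous foci than G1 cells, raw
counts mislead whenever populations differ in cell-cycle structure (e.g.
fibroblasts versus induced pluripotent stem cells). `dsbfoci` implements
the full stratified pipeline for researchers running such assays:

1. **Nucleus segmentation** — Gaussian preprocessing (σ = 1 px), a
   two-level Otsu threshold feeding hysteresis (lower level = low
   threshold, upper level = seed), 26-connected labelling with minimum
   size (2000 voxels) and border filtering.
2. **Focus counting** — the extended-maxima (h-maxima) transform:
   regional maxima of the grayscale reconstruction of *v − h* under *v*,
   with spot height threshold h = 80 counts and maximum spot size 800
   voxels; counts per nucleus by centroid assignment.
3. **EdU gating** — per-nucleus total EdU intensity, one-dimensional Otsu
   threshold per slide; cells below the threshold are G1 (EdU-negative),
   the rest S/G2.
4. **Statistics** — per condition × phase means ± SEM (SD/√n) and n,
   fold changes and percent increases, Student's t, one-way ANOVA with
   Tukey HSD, and post-irradiation time courses (percent of foci
   remaining at 2 h and 6 h relative to the 0.5 h peak).
5. **Synthetic imaging** — a ground-truth generator emulating the target
   acquisition (30 slices × 3 µm, 1392 × 1040 px at 124 nm/px): Poisson
   foci counts per phase, ellipsoidal nuclei, diffraction-scale spots,
   bimodal EdU totals. Every stage is validated by parameter recovery
   against this truth.

A transcription of the reference per-condition summary table (mean foci
per cell ± SEM and n, per line × passage × marker × treatment × phase)
ships as `table1()` and drives the worked examples and simulations.

## Worked example

```r
library(dsbfoci)

# a fibroblast-like virtual slide: mostly G1 cells, few spontaneous foci
cond <- condition_params(line_id = "hDF", marker = "gH2AX",
                         lambda_g1 = 1.13, lambda_sg2 = 29.9,
                         frac_g1 = 0.872, n_cells = 60)
render <- render_params(shape_zyx = c(12L, 512L, 512L))  # desk-scale fields

sa <- analyze_slide(cond, render, seed = 1)   # simulate → segment → count → gate
sa
#> <slide_analysis> hDF/gH2AX: 60 cells over 10 fields, 90.0% EdU-negative

summarize_foci(sa$cells)
#> # A tibble: 2 × 8
#>   line_id marker dose_gy time_h phase mean_foci   sem n_cells
#>   <chr>   <chr>    <dbl>  <dbl> <chr>     <dbl> <dbl>   <int>
#> 1 hDF     gH2AX        0      0 G1         1.22 0.131      54
#> 2 hDF     gH2AX        0      0 SG2       26.5  2.20        6
```

The G1 mean recovers the generative rate 1.13 and the S/G2 mean the rate
29.9, within sampling error; the gate recovers the 87.2% EdU-negative
fraction used to generate the slide. Fold-change arithmetic on the
packaged table reproduces the reference numbers:

```r
tab <- table1()
g1 <- subset(tab, line == "hDF" & marker == "gH2AX" & phase == "G1")
format_fold(fold_change(g1$mean_foci[g1$treatment != "control"],
                        g1$mean_foci[g1$treatment == "control"]))
#> [1] 18
```

`autoplot()` methods cover gates (`edu_gate`), summaries
(`foci_summary`); `plot_time_course()` and `plot_projection()` cover
kinetics and quick-look renderings. `tidy()`/`glance()` methods follow
broom conventions. A thin CLI over the same functions lives at
`inst/cli/dsbfoci.R` (`simulate`, `segment`, `count`, `gate`, `stats`,
`run` subcommands on YAML configs).

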