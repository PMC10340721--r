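# mitoquant

Quantitative 3D fluorescence-microscopy analysis of mitochondrial
dynamics, autophagy and mitophagy — with a synthetic-data generator that
makes every stage testable against exact ground truth.

## The problem

Live-cell studies of mitochondrial quality control ask three quantitative
questions of multi-channel z-stacks:

1. **How dynamic is the mitochondrial network?** Fission and fusion events
   between consecutive 3D frames of a time lapse, plus structure counts
   and mean structure volume (µm³) per frame.
2. **What happens to the autophagy pathway intermediates?** Counts and
   volumes of autophagosomes (AP, GFP-LC3⁺), lysosomes (LYS,
   LysoTracker⁺) and autolysosomes (AL, both).
3. **Is mitophagy engaged?** Counts and volumes of the mitophagy puncta —
   automitosomes (AM, LC3+Mito), mitolysosomes (ML, Lyso+Mito) and
   automitolysosomes (AML, all three) — plus a regression-adjusted
   colocalisation (RACC) map of the mitochondria/lysosome channel pair.

`mitoquant` implements the full chain: binarization
(denoise → contrast → Otsu/fixed threshold → size filter), 26-connected
3D labelling and morphometrics, an overlap-graph fission/fusion event
detector and localiser, seven-class voxel-overlap colocalisation
classification, the RACC map with penalisation angle θ
(`value = max(0, 1 − d/D(θ)) · (a+b)/2` with `D(θ) = (√2/2)·θ/90°`, `d`
the orthogonal-regression residual in normalised intensity space), and
hierarchical statistics: per-cell frame averaging, group mean ± SEM,
one-way and two-way fixed-effects ANOVA with Fisher's LSD post-hoc
comparisons.

Event counting uses the overlap-multiplicity convention (a 1→n split is
n−1 fissions), which makes the bookkeeping identity
`count(t+1) − count(t) = fissions − fusions` exact on clean transitions —
the property the test suite asserts.

Because raw data of this kind are typically not deposited, the package is
organised around `simulate_mito_timelapse()`, `simulate_vesicle_stack()`
and `simulate_experiment()`: generators that emulate the acquisition
geometry (10 slices × 0.25 µm × 9 frames for the time lapse; ≥12 slices ×
0.35 µm, three channels, for vesicles) and script ground-truth events and
classes into the rendered stacks.

## Worked example

Simulate a three-group experiment (control, low dose elevating the
mitophagy classes, high dose as a null for those classes; 9 cells per
group), run the full pipeline and look at the AML contrast:

```r
library(mitoquant)

res <- run_demo(seed = 1, out_dir = "demo_out",
                groups = c("Con", "LM", "HM"), n_cells = 9,
                modality = "vesicle")

subset(res$summaries, metric == "AML_count")
#>    group    metric n      mean       sem sem_defined
#> 13   Con AML_count 9  7.444444 0.3379313        TRUE
#> 14    HM AML_count 9  7.888889 0.3513642        TRUE
#> 15    LM AML_count 9 28.333333 1.2692955        TRUE

res$anova$AML_count$comparisons
#>   group1 group2    estimate       se           t            p significant
#> 1    Con     HM  -0.4444444 1.110185  -0.4003338 6.924520e-01       FALSE
#> 2    Con     LM -20.8888889 1.110185 -18.8156863 7.122760e-16        TRUE
#> 3     HM     LM -20.4444444 1.110185 -18.4153525 1.155695e-15        TRUE
```

The low-dose group's AML count is recovered at its simulated elevation
(≈28 vs ≈8 puncta per cell) and is the only comparison Fisher's LSD flags:
the estimate column is the mean per-cell count difference, `se` uses the
pooled residual mean square, and `p` is the unadjusted LSD p-value.

The same pipeline object carries every other metric (per-class counts and
mean volumes in µm³, mitochondrial morphometrics, RACC summaries) in
`res$measurements`, and `run_demo(..., modality = "both")` adds the
time-lapse fission/fusion metrics with their two-way
(treatment × event type) ANOVA.

A thin command-line wrapper with `demo`, `run-all` and `stats` commands is
installed at `inst/scripts/mitoquant.R`.

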