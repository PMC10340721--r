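---
title: "Quantifying mitochondrial dynamics, autophagy and mitophagy in 3D: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial dynamics, autophagy and mitophagy in 3D: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mitoquant` quantifies three linked aspects of mitochondrial quality control
from multi-channel 3D fluorescence z-stacks: the remodelling dynamics of the
mitochondrial network (fission and fusion events in time-lapse data),
the pool sizes and volumes of autophagy pathway intermediates
(autophagosomes, lysosomes, autolysosomes), and mitophagy intermediates
defined by organelle colocalisation (automitosomes, mitolysosomes,
automitolysosomes). Because live-cell microscopy data of this kind are
rarely deposited, the package ships a synthetic-data generator with exact,
scripted ground truth; every analysis stage is validated against it.

## The measurement model

### Voxels, masks and volumes

All stages operate on 3D intensity arrays indexed `[z, y, x]` (1-based)
with explicit physical voxel sizes. Two acquisition presets mirror a
typical confocal live-cell protocol: time-lapse mitochondrial imaging with
10 optical sections at a 0.25 µm z-step over 9 frames acquired ≤ 30 s
apart, and static three-channel vesicle imaging with 12 sections at a
0.35 µm z-step. The lateral pixel size is not fixed by such protocols;
the default of 0.1 µm is typical Nyquist-range sampling for a 100×/1.4 NA
objective and is configurable. Structure volume is always
`voxel_count × voxel_z_um × voxel_xy_um²`, reported in µm³.

Connectivity is 26-neighbourhood in 3D throughout — the standard choice
for sparse fluorescent structures — stated once here and used everywhere
(labelling, size filter, event detection, oracle tests alike).

### Binarization

`binarize()` runs denoise → contrast adjustment → threshold:

* **Denoise** — default *none*. At this sampling, tubule diameters are
  about 5 px and a genuine fission gap is one voxel wide: measured on the
  generator's geometry, a 1-voxel Gaussian closes such gaps and biases
  structure counts, while the default rendering needs no smoothing for
  exact mask recovery. Gaussian (σ in voxels, axially scaled by the
  anisotropy) and Richardson–Lucy deconvolution (Gaussian PSF) remain
  available for real, lower-SNR material.
* **Contrast** — percentile rescale of `[p_low, p_high]` to `[0, 1]`,
  defaults 0.1/100. The upper anchor is deliberately the maximum: on a
  sparsely populated puncta channel (well under 1% foreground) the 99.9th
  percentile lies *inside the background noise*, and anchoring there
  stretches noise across the full range and defeats thresholding. With
  hot-pixel-prone cameras, lower `p_high`.
* **Threshold** — global Otsu per channel per volume (default), or a fixed
  value. A constant image has no Otsu threshold and raises a
  "degenerate histogram" error rather than guessing.

`apply_size_filter()` then removes connected components below
`min_voxels`. The cutoff used for the GFP-LC3-like channel is a package
decision (default 8 voxels ≈ 0.03 µm³ at the vesicle geometry), as
published pipelines of this type state that a size filter was used but not
its value.

`detect_puncta()` adds a channel-level guard the raw chain cannot provide:
Otsu presumes a bimodal histogram, so on a channel containing *no* real
signal it splits the noise and floods the field. A channel whose 99.99th
intensity percentile sits less than 8 robust noise scales above the median
— the noise scale comes from the upper quartile, because zero-clipping of
the detector deflates the MAD — or whose thresholded foreground exceeds
25% of the volume, is treated as background-only and yields an empty
puncta set.

### Fission and fusion events

Between two consecutive binarized frames, `detect_events()` builds the
bipartite overlap graph of labelled structures (an edge when two
structures share at least `min_overlap_voxels` voxels; default 1, raise it
to suppress flicker at high noise). A frame-*t* structure overlapping
*n* ≥ 2 frame-*t+1* structures yields *n* − 1 fission events; dually, a
frame-*t+1* structure overlapped by *m* ≥ 2 frame-*t* structures yields
*m* − 1 fusions. This multiplicity convention makes the bookkeeping
identity exact on clean transitions:
`count(t+1) − count(t) = fissions − fusions`. An event is localised at
the midpoint of the centroids of the two overlap regions involved
(largest-overlap counterpart as the principal), snapped to the nearest
voxel of the union footprint of the participating structures — so the
location is always inside tissue the event concerns. Structures with no
counterpart in the other frame are reported as appearances or
disappearances and never counted as events, since abundance loss (e.g.
mitophagic elimination) is a different observable probed experimentally,
not algorithmically.

The event detector is a re-derivation against the observable contract of
mitochondrial event localisation — counts, locations, structure counts and
volumes — not a port of any particular plugin's internals. Whether an
event spanning more than two structures should count once or
multiple times is genuinely open; the *n* − 1 convention is declared, not
inferred, and is what the generator and the tests both assume.

### Colocalisation classes

`classify_puncta()` assigns every punctum to one of seven classes by voxel
overlap of binarized masks (≥ `min_shared_voxels`, default 1): AP
(LC3 only), LYS (LysoTracker only), AL (LC3+Lyso), MITO (MitoTracker
only), AM (LC3+Mito), ML (Lyso+Mito), AML (all three). Intensity-level
colocalisation is deliberately left to the RACC map; the class calls
follow the binarized-object pipeline. Two conventions are supported
because published pool sizes rarely state whether single-channel pools
exclude colocalised vesicles:

* **exclusive** (default): every punctum contributes to exactly one class,
  so `AP + AL + AM + AML = total LC3 puncta` — a partition property the
  tests assert on every run;
* **inclusive**: pairwise classes counted irrespective of the third
  channel.

Composite-vesicle volume is attributed to the defining channel's punctum
(LC3 for AP/AL/AM/AML, LysoTracker for LYS/ML, MitoTracker for MITO), so
each class has one canonical volume series.

### The RACC map

`racc_map()` produces a regression-adjusted colocalisation map for a
channel pair: both channels are min–max normalised over the evaluated
voxels (making the map invariant to affine intensity rescaling of either
channel), an *orthogonal* (total-least-squares) regression line is fitted
to the paired intensities (making the map invariant to channel order,
unlike ordinary regression), and each voxel gets

value = max(0, 1 − d/D(θ)) · (a + b)/2,  D(θ) = (√2/2) · θ/90°,

where `d` is the voxel's perpendicular distance to the line in the
normalised intensity plane. The linear-in-distance kernel with the
θ-scaled cutoff is this package's concrete definition of the penalisation
angle: at `d = 0` there is no attenuation, larger θ penalises scatter
less, and the brightness factor `(a+b)/2` darkens on-line but dim voxel
pairs. It is parameter-compatible with the customary θ = 45° working
point and satisfies the qualitative contract of regression-adjusted
colocalisation mapping; it is documented as RACC-like, not as a port.
`racc_summary()` reduces a map to its in-mask mean so cells and groups can
be compared on one scalar. Maps are computed over the full 3D stack by
default; pass a per-slice mask to restrict evaluation.

### Hierarchical statistics

The statistics enforce the averaging hierarchy of live-cell designs: frame
values are averaged within each cell first, and only per-cell values enter
group statistics (frame-level values never reach an ANOVA). Group
summaries are mean ± SEM with the sample-SD SEM; `n = 1` yields a flagged
undefined SEM. Event dynamics (one value per cell per event type) are
analysed with a crossed two-way fixed-effects ANOVA
(treatment × event type); all other metrics with one-way ANOVA. Both are
followed by Fisher's LSD: all pairwise t-tests on the pooled residual mean
square and residual degrees of freedom, *with no multiplicity
correction* — that is what LSD is, and users should weigh the resulting
per-comparison error rate. Whether event type should instead be a
within-cell repeated measure is not decidable from the reporting such
studies give; the plain crossed model is implemented and the ambiguity
recorded here. Replicate experiment identity is not modelled as a
blocking factor, matching the analysis style the pipeline reproduces.

## The synthetic-data generator

`simulate_mito_timelapse()` renders a network of `n_tubules` non-touching
tubules (persistent random-walk centre lines, constant radius, default
0.25 µm) and then edits the ground-truth mask between frames: a scripted
*fission* erases a separating slab one voxel thick (slightly thicker for
oblique cuts, so 26-connectivity is truly broken) through one structure,
retrying cut positions until exactly two children remain; a scripted
*fusion* draws a bridging cylinder between the closest surface points of
two structures, rejecting bridges that would touch a third structure.
Auto-picked targets are restricted to structures untouched by an earlier
event of the same transition: a fusion whose product is re-split before
the next frame is fundamentally unobservable in a frame-pair overlap
graph, and allowing such chains would make scripted counts untestable.
Scenarios drawn from group-level rates use `on_unrealisable = "skip"` so
an infeasible event is dropped (the ground truth reflects realised events
only); explicitly scripted schedules keep the hard error.

`simulate_vesicle_stack()` places puncta of the seven classes on a
jittered grid whose pitch guarantees zero voxel contact between distinct
puncta — a determinate alternative to rejection sampling that also yields
a clean capacity bound (exceeding it raises a placement error). Within a
colocalised punctum, the channel spheres share a scripted fraction of
their volume (equal radii; the offset distance inverts the sphere–sphere
lens-volume formula), so overlaps are 0 or substantial by construction and
class labels are exact ground truth.

Rendering is the same for both modalities: binary mask × amplitude,
PSF-like anisotropic Gaussian blur (σ_xy = 0.5, σ_z = 0.4 voxels — an
acknowledged approximation; full optical PSF modelling is out of scope),
then Poisson photon noise (`rpois(I/g)·g`, default gain 1) and Gaussian
read noise (default SD 2 at amplitude 100). These defaults were chosen
once so that the default binarization recovers the ground-truth mask
*exactly* on noise-free renders — the half-maximum level set of the
blurred mask coincides with the mask for structures of radius ≥ 2 voxels
— and remains near-exact at default noise; the test suite asserts
voxel-wise F1 ≥ 0.99 there. Abstract SNR controls are all the generator
exposes; laser power or detector physics (bleaching, blinking) are not
modelled, and TMRE-like intensity carries no membrane-potential meaning.

What passing tests on these synthetics do *not* show: robustness to
illumination gradients, cell movement between frames (real acquisitions
this fast are nearly aligned, and registration is explicitly out of
scope), organelle shapes beyond tubes and spheres, chromatic offsets, or
probe crosstalk. Results on real stacks depend on those factors and on a
PSF the generator only caricatures.

## Problem sizes and determinism

All randomness flows from a single integer seed per simulation
(`with_seed` restores the caller's RNG state); `simulate_experiment()`
derives per-cell seeds from the master seed, so a dataset, its manifest
and the whole report bundle are bit-reproducible. The bundled demo runs
three to six groups of 9 cells each — the per-group sample size of the
study design it mirrors — on 160 px fields, with per-class punctum counts
about one third of the per-cell pool sizes such experiments report (e.g.
control AML ≈ 8 vs low-dose AML ≈ 28, preserving the ≈ 3.5× contrast and
an effect ≥ 3 between-cell SDs). These are the package's chosen problem
sizes: large enough that counts, volumes and the LSD contrasts behave like
the real quantities, small enough to run interactively.

## Known limitations

* The event detector compares consecutive frame pairs only; it does not
  track identity across more than two frames, cannot see cancelling event
  chains within one interval, and does not attempt sub-voxel localisation.
* Otsu thresholding assumes a bimodal histogram; the background-channel
  guard catches the empty-channel failure mode but not structured
  background (out-of-focus haze, autofluorescence gradients).
* The RACC attenuation kernel is a definition, not a reconstruction of any
  specific published implementation; only its qualitative contract and the
  θ = 45° working point are matched.
* Fisher's LSD makes no multiplicity adjustment by design; with many
  groups, per-family error grows accordingly.
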