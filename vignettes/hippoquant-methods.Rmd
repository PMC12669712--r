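---
title: "Methods: synthetic-data parameter recovery for Hippo-scaffold readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-data parameter recovery for Hippo-scaffold readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hippoquant` re-implements, as a reusable and contract-tested pipeline,
the quantitative procedures used to characterise a kinase scaffold of
Hippo signalling: single-cell fluorescence morphometrics, ΔΔCT relative
expression, RPPA differential ranking, signed-network route scoring, and
mass-photometry complex detection. Because the original measurements are
wet-lab observations, validation here is by *parameter recovery*: every
input has a seeded synthetic generator that records ground truth, the
generators are configured to the published effect sizes, and the pipeline
must recover those effects blind. This vignette explains the models, the
parameters that matter, the numerical choices, and what passing the
recovery suite does and does not establish about real data.

## The synthetic image model

`generate_cell_image()` renders cells as non-overlapping circular bodies,
each with one elliptical nucleus. Circular/elliptical (convex) geometry is
deliberate: it keeps every truth metric closed-form or exactly measurable
from the recorded masks, so the generator can serve as a segmentation
oracle. Real fibroblasts are irregular; exactness of the oracle was chosen
over realism.

Per condition, an *effect profile* fixes the generative means:

* nucleus equivalent radius (default 16 px, sd 1.5) and minor/major axis
  ratio (0.85; the knockout profile uses 0.70 — more elongated);
* nuclear centroid displacement as a fraction of the cell radius (0.05
  wild-type, 0.15 knockout), applied along a random direction;
* protein-channel intensity inside the nucleus and in the cytoplasm
  (arbitrary units; the knockout's nuclear level is 0.62× wild type,
  encoding the 38% nuclear-YAP reduction as a *ratio of channel means* —
  fluorescence units are arbitrary, ratios are what carry meaning);
* a Poisson number of straight stress fibers per cell with Gaussian
  lengths (wild type 28 px, knockout 42 px, overexpressor 20 px — the
  direction of the published effect; no pixel lengths are published);
* a constant background (20 a.u.) plus additive Gaussian noise (sd 6).

The cell radius is `max((nucleus semi-axis + 5)/(1 − displacement
fraction), 2.2 × nucleus radius)`: the nucleus plus its displacement must
fit with margin, and there must be enough cytoplasm to host fibers of the
profile's length scale. Fibers are drawn with a ~6 px clearance from the
cell boundary so their recovery is not confounded with the boundary
itself. The noise model is additive Gaussian on a constant background (no
Poisson shot term): adequate for stressing the segmentation, one fewer
parameter. Pixels are dimensionless and intensities floating point; no
acquisition bit depth or physical pixel size is modelled.

Ground truth records the label masks and per-cell records *measured on
the noise-free rendering with the true masks*, which makes the
self-consistency invariant (re-measuring truth masks reproduces truth
records to 1e-6) meaningful and puts truth and pipeline on the same
measurement conventions.

What the generator does **not** emulate: irregular cell shapes, chromatin
texture, out-of-focus light, shading and vignetting, cell contact and
overlap, 3-D structure. Passing the recovery suite therefore shows the
*measurement chain* is correct and unbiased under the stated model; it
does not certify segmentation quality on real confocal images, where a
learned backend (the operation contracts are backend-agnostic) may be
needed.

## Segmentation and morphometrics

Nuclei: median filter (disk radius 2) on the DNA channel, global Otsu
threshold, 8-connectivity components (EBImage's 4-connective labelling
plus a union-find diagonal merge), removal of components under 50 px²,
then a distance-transform watershed to split touching nuclei. A constant
channel is a degenerate-input error, not an empty result.

Cell bodies: Otsu threshold of a median-filtered actin+protein composite
(median, not Gaussian, so the boundary does not shift), morphological
closing and hole filling, then marker-controlled growing from the nuclei
(`EBImage::propagate`), so each cell contains exactly its seed nucleus.
Border-touching cells are excluded from statistics — standard practice.

Stress fibers: a multiscale Hessian ridge filter (scales 1 and 2 px,
scale-normalised, most negative eigenvalue). Before filtering, the
background is filled with the median within-cell intensity so the step
edge at the cell boundary produces no ridge response of its own; the
response is then thresholded by Otsu *within* the (slightly eroded) cell
foreground. The final objects are the bright within-cell components that
carry ridge support — mirroring the pixel-classifier → object-classifier
staging of the trained backend this deterministic one replaces — filtered
to a minimum end-to-end length of 10 px.

Per-cell metrics follow the field's conventions. *Eccentricity* is the
ratio of minor to major moment-ellipse axis lengths (1 = round) — not the
conic-section eccentricity; the field is named `eccentricity_ratio` to
prevent confusion. *Solidity* is region area over the rasterised
convex-hull area; for digitisations of convex sets this is exactly 1,
which is why the concentric-circles fixture yields d = 0, e = 1, s = 1
exactly. *Nuclear displacement* is the distance between the nuclear
centroid and the centroid of the whole cell segment (the segment contains
the nucleus; with a segmented "cytoplasmic" region that includes the
nucleus this is the natural reading). Fiber lengths are end-to-end
(max-Feret) lengths rather than moment-ellipse major axes: for a thin
straight object the moment axis overestimates length by ~15%
(4·sd of a uniform line = 1.155 L), and the generator draws straight
fibers of known length.

Numerical floors: 5% relative agreement with ground truth holds for every
per-cell field on noise-free images, with one caveat — the wild-type
nuclear displacement is itself only ~1.5 px, and 5% of that is below the
resolution of binary-mask centroids, so the recovery tests use a 0.3 px
absolute floor for this single field.

Condition effects pool cells across images within a condition (the
experiments emulated pool ≥100 cells from three biological samples) and
use the Mann–Whitney rank-sum test for two groups and Kruskal–Wallis for
more, reported with the percent change of group means.

## ΔΔCT

CT values are generated as `reference_ct − log2(fold)` plus per-well
Gaussian noise; the reference gene is condition-independent. Analysis
averages technical replicates per biological sample (run), forms
ΔCT = CT(target) − CT(reference) and ΔΔCT against the mean calibrator
ΔCT, and reports fold = 2^(−ΔΔCT). The condition-level fold is the
*geometric* mean (2^(−mean ΔΔCT)): it makes the calibrator exactly 1 by
construction and is unbiased in log space; the SE shown is the arithmetic
standard error of per-sample folds, i.e. the error bar a fold-change bar
chart carries. Biological replicate = run; whether the published SEs are
over runs or wells is not stated, runs were chosen.

The five packaged designs encode the published expression effects (80%
and 93% reductions of the YAP targets CyR61 and CTGF in knockout MEFs, an
18.8-fold YAP increase in overexpressing MEFs, 37% and 51% YAP reductions
in knockout MEFs and knockdown MCF-7 cells) at 3 runs × triplicates with
CT noise sd 0.15 cycles. At that depth a single simulated experiment
recovers the weaker folds with ~6% sampling error, so recovery reports
average five generator seeds — this narrows variance, not bias.

## RPPA filter and ranking

Per protein, the mean log2 difference against control and a two-sided
two-sample Student t-test. The differential set is |log2FC| ≥ 1 and
p < 0.05 with **no** multiple-testing correction — the emulated analysis
states a raw p threshold; a Benjamini–Hochberg flag exists but is off by
default, and the type-I behaviour of the raw rule (~5% of null proteins)
is asserted by simulation. Ranking is by |log2FC| among filter-passing
proteins (the published "ranking" does not state its key; absolute fold
is the natural choice for a fold-filtered list), ties broken by protein
id, padded with non-passing proteins (flagged) if fewer than `top_n`
pass.

## Route scoring

Routes are simple directed paths from the scaffold (KSR1) to YAP1 with at
most 4 edges (a configurable depth; deeper routes are biologically
uninterpretable here and combinatorially explosive). Against a ranked
protein list, a route scores three disjoint counts: ranked proteins on
the route (c1); ranked proteins one protein-interaction edge from a route
node (c2); ranked proteins two edges away via a single mediator (c3).
Design choices where the emulated procedure is silent: route edges follow
direction but c2/c3 adjacency ignores it (the more inclusive reading of
"directly linked" / "accessible via a single mediator"); the three sets
are made disjoint with c1 ≻ c2 ≻ c3 precedence so the total cannot
double-count; the total is an unweighted sum, with components always
reported so any weighting can be applied downstream; edge signs
(activation/inhibition/unknown, parsed from the SIGNOR dialect) are
retained but do not weight the score — an activation-only route filter is
available. The ranked list passed in is the scoring universe (top-100 by
default downstream). Correctness is established against brute-force path
enumeration and BFS-distance oracles on random graphs, and against
planted-overlap constructions whose score is exact by construction.

## Mass photometry

Landing-event masses are modelled as a Gaussian mixture; contrasts
convert through the linear calibration mass = a·contrast + b. Fitting is
expectation-maximisation on the *raw masses* — statistically cleaner and
bin-free; the 5 kDa histogram is emitted for reporting only — with
k-means++-style seeded initialisation (three restarts per k, best
likelihood kept, which guards BIC against locally-optimal fits that
masquerade as extra components), k = 1..4 selected by BIC, and a width
floor of 1e-3 sd to prevent component collapse. A mixed sample is called
a complex when it has a peak of weight ≥ 0.1 whose centre exceeds every
peak of both individual samples by more than 2× their pooled width, and
the call reports whether that centre matches the summed dominant masses
(a 1:1 complex). The published experiment reports no numeric masses, so
this module's validation is property-based: centre recovery within 5 kDa
and weights within 0.05 for well-separated designs at n ≥ 2000.

## Pipeline and reproducibility

`run_pipeline()` validates its configuration (unknown keys rejected,
before any output is written), fans one user seed out to fixed per-stage
child seeds so stages can re-run independently yet the whole run is one
seed, and writes plain TSVs plus a JSON metadata sidecar; identical
(config, seed) runs are byte-identical. Problem sizes used throughout the
tests and recovery scripts — 512×512 images with 9 cells, 4 images ×
3 seeds per condition (≥ 100 cells each), 2000–3000 mass events, 100
random graphs of ≤ 8 nodes, 200-seed power/type-I simulations — were
chosen as the smallest designs at which the recovery tolerances are
comfortably interpretable.

## Known limitations

Convex single-nucleus cells only; no 3-D, no optics simulation, no
RPPA plate effects, no qPCR amplification-efficiency correction (Pfaffl);
the classical segmentation backends are deterministic stand-ins with the
same contracts as learned models but weaker robustness on real images;
route enumeration is capped (with an explicit truncation flag) on dense
networks.
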