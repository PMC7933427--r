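---
title: "Quantifying a neuropeptide code: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a neuropeptide code: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dorsalcode)
```

## The problem

Multiplex single-molecule fluorescence in situ hybridisation (RNAscope)
renders individual transcript clusters as diffraction-limited "dots",
up to three probes per section. Mapping which neuropeptide genes are
co-expressed by which dorsal horn neurons, and in which laminae those
neurons sit, reduces to a chain of image-quantification steps:

1. segment nuclei (primary objects) and expand them into somata
   (secondary objects) — the "cell" of all downstream counting;
2. detect signal dots per probe channel and assign each to the cell it
   lies in, giving integer *dots per cell*;
3. calibrate, per channel and probe combination, a background threshold
   from a matched negative-control section (a probe against a bacterial
   gene), and call cells *positive* (above background) or *high*
   (clearly above background);
4. summarise calls as triple-probe Venn counts per animal, pairwise
   co-expression matrices, and per-lamina counts after aligning each
   section to a reference template;
5. separately, filter gene × sample count matrices from a
   cell-type-specific sequencing screen (TRAP translatome) by
   normalised-count and enrichment criteria and measure the congruence
   of two screens.

`dorsalcode` implements this chain as composable functions, plus a
synthetic tissue generator with exhaustive ground truth so every stage
is testable without microscopes or sequencers.

## Coordinate convention

Pixel coordinates are 0-based, origin at the top-left corner, x to the
right (columns), y down (rows); positions refer to pixel centers.  An
image matrix is indexed `[y + 1, x + 1]`.  This convention is used by
the simulator, the detectors, the label maps and all tables.

## Segmentation

`detect_nuclei()` follows the semantics of CellProfiler-style primary
object identification: a global Otsu threshold computed on the
(optionally Gaussian-smoothed) nuclear channel is multiplied by a
*threshold correction factor* and clipped to explicit lower/upper
bounds; foreground is strictly above the effective threshold.  Touching
nuclei are split by a watershed on the Euclidean distance transform
(declumping), and objects outside a diameter range are discarded.  The
original pipeline's exact declumping settings and diameter ranges are
not public, so all of these are configuration, not constants.  Border
objects are kept by default; exclusion is a flag.

`expand_to_soma()` assigns every background pixel within `max_distance`
of a nucleus to its *nearest* nucleus region (Euclidean distance to the
region, not to the centroid), with ties going to the lower label.  Each
soma therefore contains its nucleus, somata never overlap, and the
boundary between neighbouring somata lies on the equidistant line.  The
expansion distance is a required-to-review parameter (default 4 px in
the simulator, 10 px in `segmentation_params()`-free use): the source
workflow does not state the value it used.

Image-processing primitives (Otsu, Gaussian blur, exact distance
transform, watershed, connected components, convolution) come from
EBImage; the module's behaviour is pinned by oracle tests (brute-force
nearest-nucleus scans, analytic disc geometry, watershed splits on known
two-disc images).

## Spot detection and dots per cell

`detect_spots()` computes a scale-normalised Laplacian-of-Gaussian blob
response (scale `log_sigma`, default 0.6 px, matched to the rendered
point-spread sigma of 0.7 px), thresholds it with the same
correction-factor-and-bounds scheme (per-slide adaptation is expressed
as one parameter set per image batch), takes 8-neighbourhood local
maxima, and suppresses maxima closer than `min_separation` to a
stronger one.  Reported positions are sub-pixel (intensity-weighted
3 × 3 centroid), but cell assignment uses the *rounded* pixel — a plain
label-map lookup, reproducible and order-independent.
`dots_per_cell()` tabulates assigned spots per soma label and channel,
keeping zero-dot cells; spots over background (label 0) are excluded
from counts but never dropped from the table.

Two numerical choices deserve note:

* **NMS radius 1.2 px.** Distinct dots are generated at ≥ 3 px
  separation (see below), so their response-peak pixels are at least
  2 grid units apart; a single blob, however, can produce two
  axis-adjacent equal maxima when its center falls exactly between
  pixels.  A suppression radius strictly between 1 and √2 removes those
  duplicates without ever merging two real dots.
* **What is "one dot" when signal clumps** is not defined by the
  assay; this package documents its merge behaviour (closer than the
  NMS radius → one detection) rather than claiming to match any
  specific original.

## Background calibration and positivity

`background_threshold()` takes the dots-per-cell distribution measured
in the matched negative control and returns its 90th percentile using
the *nearest-rank* convention (rank `ceiling(p/100 · n)` of the sorted
values).  Dots per cell are integers; interpolating percentile
conventions would produce unattainable fractional thresholds, while
nearest-rank thresholds are always observed values.  A cell is
**positive** when its count is *strictly above* this threshold, and
**high** when it is additionally strictly above 20 dots/cell.  High
implies positive: if a channel's background threshold were ever to
exceed 20, the background rule wins.  Both inequalities are strict
("above which", "> 20").  An empty negative control is an error — there
is no calibration to fall back on.

## Co-expression summaries

`venn_counts()` pools the hemisections of each animal and counts the
seven Venn regions of a three-probe combination plus the
triple-negative remainder; the regions partition the cells by
construction and by test.

`pairwise_matrix()` computes, per animal, `N_g` (cells expressing the
row gene) and `N_gh` (cells co-expressing both), forms
`F[g,h] = 100 · N_gh / N_g`, and averages `F` unweighted across animals
— ratios first, means second.  Reciprocity
(`F[g,h]·N_g = F[h,g]·N_h = 100·N_gh`) holds on unrounded per-animal
counts and is asserted continuously in the test suite.  At the
stringent level the > 20 rule is applied to **both** genes of a pair by
default (the symmetric definition keeps reciprocity meaningful); the
asymmetric row-gene-only variant is available via
`high_rule = "row"`.  Pairs never hybridised together in any
combination are reported as missing (`NA`), never as 0, with a warning
and a machine-readable `missing_pairs` table.

## Laminar mapping

Alignment is landmark-based: `fit_alignment()` solves the least-squares
2-D affine from ≥ 3 non-collinear landmark pairs (dorso-medial and
dorso-lateral corners plus ventral corners of the grey matter are the
default landmark set) and reports the residual RMS.  No intensity-based
registration is attempted — the source workflow does not describe one,
and landmarks are the minimal reproducible substitute.
`assign_lamina()` maps each cell centroid through the transform and
assigns it to the first lamina polygon containing it in
dorsal-to-ventral order; points exactly on a shared boundary therefore
go to the dorsal-most matching lamina, and every cell receives exactly
one label (`"outside"` if none).  Mixed "I–II border" assignments are
out of scope.  The shipped template is a stylised half dorsal horn —
a rectangular outline with five stacked bands whose relative depths
follow the lumbar cytoarchitecture — and is a synthetic stand-in for
atlas reference sections; users can supply their own GeoJSON.

## Translatome filtering

`normalize_counts()` fixes the normalised-count formula as reads per
kilobase per million mapped reads:
`raw / (library_size/1e6) / (length/1e3)`.  The screen thresholds are
interpreted on this scale: a gene is *expressed* above 10 normalised
counts and *detectable by in situ hybridisation* above 100 (named
defaults in `expressed_thresholds`), both strict, computed on group
means by default (a per-sample-minimum flag exists; which convention
the original screen used is not stated).  `de_filter()` keeps genes
with FDR ≤ 0.05 and fold ≥ 2 (inclusive, as printed) per direction;
`congruence()` reports set sizes, the intersection, and the percent of
each set recovered in the other.  FDR values are an *input*: moderated
differential-expression testing belongs to dedicated tools and is out
of scope here.  `nb_test_oracle()` — a per-gene negative-binomial GLM
Wald test with Benjamini–Hochberg correction — exists to supply FDRs
for simulated matrices with known truth and is explicitly not
equivalent to the published analyses.

## The synthetic tissue generator

`generate_tissue()` emulates, with full ground truth:

* **nuclei** as discs (radius ~ truncated normal, default mean 4 px,
  floor 1.5 px) placed without overlap inside laminar bands; each
  cell's lamina is drawn once from its population's placement weights
  and only the position is retried under crowding, so the realised
  laminar distribution is exactly multinomial;
* **somata** via the same nearest-nucleus expansion rule as the
  segmentation stage, so ground-truth somata and pipeline secondary
  objects share one geometry;
* **expression** from a mixture of populations: each population has a
  weight, per-gene Bernoulli expression probabilities, and per-gene
  negative-binomial dot counts (dispersion 0 = Poisson) — this is the
  generative co-expression structure the pipeline must recover;
* **dots** as Gaussian blobs (sigma 0.7 px, amplitude 0.5 on a 0–1
  intensity scale) placed inside the parent soma such that the rounded
  pixel and its 8 neighbours all carry the parent label — any detection
  within ~1 px of the truth maps back to the right cell;
* **background** as a uniform Poisson process per channel at
  `background_dot_rate` expected stray dots per cell-equivalent area
  (`pi·(mean nucleus radius + expansion)²`), falling inside and outside
  somata alike — which is exactly why a negative-control threshold is
  needed; the rate itself is a free parameter (default 0.5 dots/cell),
  not a claim about any real assay's background;
* **study design** defaults of 3 animals × 2 hemisections per
  combination, with one negative-control hemisection per combination.

Two deliberate deviations from a naive generative model:

* **Minimum dot separation (3 px) and capacity truncation.**  Rendered
  same-channel dots keep a minimum separation so that, in noiseless
  benchmarks, detection is provably exact (peak pixels of distinct dots
  can never become 8-neighbours).  A soma whose drawn count exceeds its
  packing capacity at that separation has the excess dots dropped, and
  its true count reduced accordingly — the ground truth always equals
  what was actually rendered (the number dropped is recorded on the
  truth object).  The fast, non-rendering path
  (`simulate_cell_table()`) has no such constraint and follows the
  mixture model exactly; statistical benchmarks use it.
* **Same expansion rule as the pipeline.**  Using the pipeline's own
  soma geometry in the ground truth is what makes "exact recovery with
  ground-truth segmentation" a meaningful, achievable specification of
  correctness for the spot stages in isolation.

What the simulator does **not** model: optics-accurate PSFs, 3-D
stacks, tissue autofluorescence, intensity variation between dots,
segmentation-hostile nuclear textures, or artefact-bearing images.
Passing the recovery benchmarks therefore shows the *quantification
logic* is correct under its stated assumptions — not that any
particular microscope's images will segment cleanly.

`expected_coexpression()` gives the closed-form co-expression matrix
implied by the mixture (exact convolution of the negative-binomial dot
counts with the Poisson background against the positivity threshold),
which is the reference for parameter-recovery tests.

## Benchmark problem sizes

The shipped tests and `scripts/acceptance.R` use: one 200-cell,
3-channel, zero-noise section for exact end-to-end recovery; 1,000
random count vectors for the percentile oracle; 20 simulated studies
(2 animals × 2 hemisections × 260 cells, background 0.5 dots/cell,
negative-control-calibrated) for co-expression recovery at the
stringent level, where ≥ 95 % of gene-pair fractions must fall within
±5 percentage points of the closed form; 500 cells at 90 %/10 %
laminar placement behind a known affine for laminar recovery; and
600-gene matrices with 50 planted fold-4 genes for the enrichment
filter.  The stringent level is used for recovery because the
90th-percentile rule tolerates ~9 % false-positive calls per channel
by construction (for Poisson background at 0.5 dots/cell,
`P(X > q90) ≈ 0.09`), which inflates near-zero fractions at the "any"
level — a property of the calibration scheme itself, visible in
`expected_coexpression()` at any threshold.

## Known limitations

* The soma expansion distance, declumping parameters and diameter
  ranges of the original workflow are unknown; results depend on them
  and they must be reviewed per dataset.
* Spot merge behaviour under clumped signal is documented, not matched
  to any original.
* The affine landmark alignment cannot express non-linear section
  distortion.
* Boundary-straddling cells receive a single lamina by the dorsal-most
  rule rather than fractional assignment.
* The NB reference test is a plain per-gene GLM; it has no dispersion
  moderation and should not be used on real sequencing data.
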