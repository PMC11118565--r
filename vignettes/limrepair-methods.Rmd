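---
title: "Quantifying LIM-protein assemblies and actin repair: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LIM-protein assemblies and actin repair: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limrepair)
```

# The analysis problem

LIM-domain proteins such as zyxin recognise mechanically strained F-actin.
In reconstituted TIRF assays they assemble into elongated structures on
filaments under myosin-generated force, recruit partner proteins (VASP,
alpha-actinin), phase-separate into condensates, and drive the repair of
laser-ablated contractile bundles. `limrepair` implements the image
quantifications these experiments need — detection and gap-tolerant
tracking of LIM-protein objects, topological classification against the
actin channel, local-background enrichment, partner-binding events,
droplet segmentation and FRAP traces, bundle thickness, and strain-site
recovery kymographs — together with a synthetic-movie generator that
plants exact ground truth so every stage is testable without raw data.

# The patch pipeline

## Mask recipe

Each channel is processed per frame as: rolling temporal average (3
frames) → Gaussian blur (sigma 1 px) → Sobel gradient magnitude →
auto-threshold (Li for actin, Yen for the LIM channel; 256-bin histograms
over the frame's min–max range) → hole filling → two binary erosions →
(LIM only) 10–150 px area bandpass and 8-connected labeling.

The two erosions deserve explanation. A filled Sobel-edge band always
overshoots the true object: the gradient response of an edge has finite
width, so the band's outer rim lies outside the object and filling it
dilates the mask. We measured the overshoot at roughly 1–3 px per side
depending on noise level. The single-frame alpha-actinin recipe
(`coloc_noatp_lastframe()`) erodes once for exactly this reason; for the
movie pipeline two erosions restore planted geometry to within ±1 px both
in the noiseless limit and at object SNR ≈ 3 (where the threshold already
sits higher and the band is tighter). `post_erode` is a parameter; setting
it to 0 reproduces the raw fill behaviour.

A practical consequence of the fixed 10–150 px bandpass: at the default
0.0653 µm/px and ~3 px object width, trackable LIM objects are capped
near 25 px (~1.6–1.8 µm) in length — longer objects' masks exceed 150 px
and are discarded. Planted-object studies respect this envelope.

## Tracking

Objects are linked into trajectories through an overlap graph: object A
in frame *t* connects to object B in frame *t′ > t* when their pixel
footprints intersect and the number of missing frames between them
(*t′ − t −* 1) is at most the gap window (default 3 frames, i.e. 9 s at
3 s/frame). Objects with no neighbour anywhere in the surrounding window
are non-persistent and discarded. Connected components, found by an
iterative depth-first traversal, become trajectories; blink gaps of up to
3 frames therefore never split a trajectory and gaps of 4 or more always
do. An independent graph-reachability oracle verifies this partition
exactly on randomized instances.

Note one subtlety: the temporal rolling average blurs a planted g-frame
blink into a (g − 2)-frame detection gap, because the averaged frames
adjacent to the gap still carry one third of the object's intensity. Gap
semantics are therefore a property of the linker operating on per-frame
detections; end-to-end, the effective split boundary shifts by two
frames. The package exposes `planted_detection()` to study the linker on
exact ground-truth masks.

Gaps and isolated outliers inside a linked trajectory are repaired by
copying the preceding frame's record (flagged `filled`). The outlier rule
— an area or centroid jump beyond 5× the trajectory's median absolute
deviation, with small absolute floors so exactly-constant trajectories
still expose outliers — is our own declared convention; the original
criterion is not specified anywhere we could follow.

## Filtering and classification

Trajectories are kept when they overlap the actin mask in ≥ 75% of their
frames and reach a maximum local-background enrichment ≥ 1.3 (dimmer
objects cannot be tracked reliably). Each frame is then classified from
its actin-overlap topology: two or more connected overlap regions →
`bridge` (we read a multi-fragment span as still bridging; the count
n > 2 is not specified by the source convention and is logged); one
region with ≥ 70% fractional overlap (inclusive) → `actin_bound_patch`;
one region below 70% → `tail`; none → `unbound`. Trajectories split at
class transitions, and each maximal constant-class run is summarised
separately.

## Lengths

"Maximum length" defaults to the maximum Feret (caliper) diameter of the
object's pixel set, which equals the geometric end-to-end length of an
elongated object. The more common regionprops alternative — the
major-axis length of the moments-matched ellipse — systematically reads
~15% long on rectangular objects (the 4-sigma convention maps a length-L
rectangle to 1.155 L), which would corrupt recovery of planted lengths;
it remains available via `length_measure = "ellipse"`.

## Enrichment

Enrichment is the object's mean intensity divided by the mean of its
local background, the ring produced by 3 dilations of the object mask
minus the mask and any other detected objects. Two biases matter when
interpreting absolute values: segmentation error transfers directly into
the ratio (a mask 1 px too wide dilutes a ratio-2 object by ~5–10%), and
partial-volume pixels at the object boundary dilute the mask mean under
realistic (anti-aliased or PSF-blurred) rendering. The estimator itself
is validated on exact masks of hard-edged planted objects, where it
recovers ratios in [1, 4] to machine precision without noise and within
a few percent under Poisson noise.

# Partner-protein presets

The three colocalization analyses are presets of one machinery
(`coloc_preset()`):

* **vasp** — actin thresholded directly (Otsu, ≥ 4 px); the LIM edge-mask
  times the actin mask defines the patch substrate; partner = Yen × actin
  mask (≥ 4 px). Events on the patch substrate and on its complement
  (bare actin) partition the partner signal, so nothing is
  double-counted. Events below enrichment 1.0 are dropped. Search window
  9 s, converted to frames by the movie's frame interval (it can be
  pinned in frames via `gap_window` when a dataset's sampling differs).
* **actinin_atp** — actin by Yen (≥ 10 px), LIM by triangle, partner by
  Yen (both × actin, ≥ 4 px), 15 s window, enrichment floor 1.3.
* **actinin_noatp** — single-frame analysis of the final frame: actin by
  Li (≥ 5 px); LIM and alpha-actinin channels Sobel → threshold (Yen;
  Li or Yen for alpha-actinin by construct) → fill → erode once → × actin
  → ≥ 3 px; colocalization is the product of the two masks.

Intensity thresholds assume sparse bright objects; when a threshold
lands below the background (for instance when the only structure is
darker than background) the resulting near-full-frame "mask" is treated
as empty.

Binding events at or below 2 s are `transient`, longer ones `stable`
(the observed transient population spans 1–2 s; the bound is closed at
2). Because transient lifetimes sit at the sampling limit, summaries
report mean lifetimes rather than half-lives for binding events. Counts
across trials of unequal length can be restricted to a common imaging
period (`equal_period_s`).

The actin fold-increase measurement integrates the rolling-ball
background-subtracted actin channel in fixed 20 × 20 px boxes, divides by
the mean of the first 5 frames, and pairs patch boxes with equal numbers
of control boxes sampled from patch-free actin regions. Note the baseline
must be non-zero: a box with no actin signal after background subtraction
is an error, not a fold change of zero.

# Condensates and FRAP

Droplets are the intersection of per-channel Otsu masks (objects ≥ 20 px
per channel); the area fraction is droplet pixels over field pixels.
Per-droplet enrichment divides the mean intensity inside the mask by the
dilated-ring background, excluding droplets smaller than 0.18 µm² or with
enrichment below 1.1. The area cutoff is configured in physical units
and converted by pixel size: the printed pixel-unit equivalent of this
cutoff is internally inconsistent, so µm² is authoritative here.

FRAP traces are extracted from circular ROIs after full-field
histogram-matching bleach correction and min–max normalized per trace.
With that normalization the post-recovery plateau directly estimates the
mobile fraction, independent of bleach depth. Histogram matching assumes
the field's intensity distribution is stationary up to a global decay;
it tolerates photobleaching a small minority of droplets (≲ 10% — we
verify unbleached-droplet traces stay flat within 5% in that regime) and
degrades when the bleached population is a substantial fraction of all
bright pixels. An exponential-recovery fit (`frap_fit_exponential()`) is
provided as an optional extension; the normalized traces are the primary
output.

# Bundles and strain sites

The bundle thickness index of frame *t* is the number of binary erosions
(3 × 3 element) needed to shrink frame *t*'s actin mask (Otsu, ≥ 50 px)
to at most the first frame's mask area — an integer proxy for thickness
growth that is exactly hand-computable on rectangle phantoms.

Strain sites are quantified through kymographs: intensity sampled at 1 px
spacing along a line across the ablation site, bilinearly interpolated
and averaged over a 3 px line width (both configurable; neither is
dictated by any source we follow). The actin trace is the kymograph's
spatial mean per time point, min–max normalized; the partner (VASP)
trace is divided by its pre-ablation mean. Repair frequencies are 2 × 2
condition × outcome tables compared by Fisher's exact test, which we
verified exhaustively against hypergeometric enumeration for N ≤ 40.

For repaired sites, the distance axis splits 10% / 80% / 10% into left
end, center and right end; segment recovery rates are ordinary
least-squares slopes within a fit window (default 40–320 s), and the
end-versus-center comparison is a paired t test across sites. The
recovery-path helper classifies the spatial pattern from segment onset
times (first crossing of 20% of final recovery amplitude, smoothed; two
frames of tolerance for "simultaneous"): center leading → `center`, both
ends leading → `both_ends`, all together → `even`, center plus one end →
`one_end_center`. Outcome and path labels are **annotations first**: the
original calls were manual, so helper output fills an advisory column and
never overwrites a provided annotation. Sites whose centroid drifts
beyond a threshold are flagged for exclusion from intensity traces while
remaining countable in frequency tables.

# The synthetic-movie generator

`sim_scene()` describes the acquisition: field size, pixel size
(default 0.0653 µm/px — derived from the one printed field calibration,
1440 × 965 px spanning 94 × 62 µm; the TIRF systems' own pixel size is
not documented, so treat this default as an inference and override it
per instrument), frame interval, per-channel uniform backgrounds, an
optional 2D illumination field, Gaussian PSF, photon scale, global
per-frame bleach factor, Poisson shot noise and a camera offset
(default 0, i.e. offsets are assumed subtracted at import). Rendering is
ideal intensity → illumination × (background + objects) → PSF blur →
bleach decay → Poisson sampling → offset. One seed makes the full movie
bit-reproducible.

Planted objects carry their own ground truth: class, per-frame geometry,
visible frames (blink gaps are just missing frames), enrichment ratio
over the channel background, and for strain sites the recovery path and
per-segment rates. The bridge/tail/patch geometries realise their
topologies directly — a bridge's LIM segment overlaps two actin
fragments separated by a central gap, a tail overlaps one fragment at
one end, a patch lies fully on actin — so planted topology maps
one-to-one onto the classifier's rule. Bridge geometry needs the actin
gap (40% of the LIM length) to stay wider than the mask growth of
segmentation, i.e. LIM segments ≳ 20 px.

Edge rendering is per object: moving filaments and droplets are
anti-aliased (sub-pixel motion must not strobe, and PSF-like soft edges
are what histogram matching and droplet segmentation meet in practice),
while patch-like objects default to anti-aliased but can be planted
hard-edged, which makes the mean intensity over the planted mask equal
the planted ratio exactly — the right construction for validating the
enrichment estimator in isolation.

Object SNR is defined as amplitude over shot noise at the object,
a / sqrt(a + B) for amplitude a on background B photons;
`snr_enrichment`-style inversion picks the enrichment that realises a
requested SNR.

What the generator does **not** emulate: motor mechanochemistry and
filament buckling, LIM polymerisation kinetics, filament crossings and
dense clutter, condensate fusion/wetting physics, read noise (off by
default, configurable), and sCMOS fixed-pattern artifacts. Passing the
recovery studies therefore demonstrates correctness of the measurement
chain, not robustness to every pathology of real data.

# Numerical choices

* Histograms for thresholding: 256 bins over min–max (the 8-bit
  convention of the reference implementations); Li's method iterates the
  cross-entropy fixed point on raw values with a positivity shift.
* Morphology: 3 × 3 square structuring element throughout; hole filling
  via border-connected background complement; 8-connectivity default for
  labeling (thin diagonal structures fragment under 4-connectivity);
  both connectivities available.
* Rolling-ball background: grayscale opening with a flat disc (radius
  50 px default); constant and linear backgrounds are removed exactly,
  structures smaller than the disc survive.
* Histogram matching: exact rank mapping (equal pixel counts per frame),
  so a planted global exponential decay inverts to quantization error.
* Kymographs: bilinear interpolation; rolling means use truncated
  windows at series edges; registration is integer-pixel phase
  correlation (translation only — rotation is out of scope).
* Degenerate inputs error loudly rather than silently returning zeros:
  constant frames cannot be thresholded, constant traces cannot be
  normalized, empty background rings cannot define enrichment.

# Validation problem sizes

The shipped studies use: a 512 × 512 px, 8-frame field with 60 planted
objects (20 per class) for classification recovery, noiseless and at
SNR 3; 50 random layouts × gap lengths 1–5 for linker gap exactness;
9 objects with staggered visible windows and lengths 18–24.5 px for
lifetime/length recovery; 16 hard-edged objects at ratios
{1.0, 1.3, 2.0, 4.0} for the enrichment estimator and dim filter; 100
randomized 32 × 32 masks, 50 random linking instances, 20 random 8-bit
images and all 2 × 2 tables with N ≤ 40 for the brute-force oracle
comparisons; 25-droplet FRAP fields at mobile fractions {0, 0.5, 1};
100 noisy strain sites (rates 0.4 vs 0.2 intensity/s, 24 s onset delay)
for path classification, slope recovery and twelve 8-site paired
cohorts. These sizes were chosen to make every study's statistical
expectation unambiguous while remaining quick to re-run.

# Known limitations

* Absolute enrichments from segmented (rather than planted) masks carry
  the mask-size bias discussed above; comparisons between conditions
  analysed identically are unaffected.
* The linker joins objects by any footprint overlap; two distinct
  objects crossing paths within the gap window merge into one component
  (the per-frame deduplication keeps the larger object). Dense fields
  need a motion-model tracker, which is out of scope.
* Histogram-matching bleach correction distorts when the bleached
  population is not a small minority of bright pixels.
* Translation-only registration; rotating or flowing fields are not
  corrected.
* The recovery-path helper is advisory by design; ambiguous onset
  patterns (single leading end) map to `one_end_center` and should be
  reviewed manually.
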