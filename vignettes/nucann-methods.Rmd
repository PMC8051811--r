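---
title: "Automatic nuclei annotation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic nuclei annotation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucann)
```

## The annotation model

`nucann` automates the production of (image, instance-mask) training pairs
for nuclei segmentation networks from raw fluorescence micrographs. The
underlying model of the data is deliberately minimal: fluorescently
stained nuclei are bright, compact, roughly elliptical objects of similar
size on a dark background. Under that model, a parameter-free chain of
classical operations recovers most instances:

**Otsu thresholding.** The intensity histogram is split at the threshold
minimizing the intra-class variance
$\sigma_W^2(t) = W_0(t)\sigma_0^2(t) + W_1(t)\sigma_1^2(t)$, where
$W_k$ and $\sigma_k^2$ are the weight and variance of the background
($\le t$) and foreground ($> t$) classes. Because the total variance is
fixed, this is equivalent to maximizing the between-class variance; the
suite verifies both formulations agree candidate by candidate.
Implementation notes: candidates are the boundaries of 256 equal-width
bins over the observed range regardless of bit depth (the classical
formulation, and it avoids 65536-candidate scans on 16-bit data), but
class moments are accumulated from the exact pixel values inside each bin,
so the scan is exact whenever distinct values land in distinct bins —
in particular for any 8-bit image. Candidates with an empty class are
skipped (the criterion is undefined there, not zero); ties take the
smallest threshold, which errs toward a larger foreground — safe, because
the downstream area filter removes junk anyway. Foreground is strictly
`> t`; the choice only affects pixels exactly at the threshold. A constant
image has no two-class split and is an error by contract.

**Marker-based watershed.** The binary mask is converted to instances by
flooding the negative Euclidean distance transform from seed markers
(8-connected, deterministic FIFO tie-break; compiled in C++). Markers are
the local maxima of the distance transform, greedily thinned to a minimum
pairwise distance, with a guarantee that every connected foreground
component receives at least one marker (its distance maximum, if peak
detection found none). That guarantee forces the partition property —
output labels partition the foreground exactly, one label per marker —
which the suite checks on a hundred seeded fields. The flooding flavour
(distance-transform rather than intensity-gradient) is the canonical
choice for convex blob-like objects; the default minimum peak distance of
7 px is about 0.7 of the expected nucleus radius at the generator's scale
and is a configuration key, since it is a scale parameter, not a constant
of the method. Over-segmentation is tolerated at this stage: fragments are
small and the area filter removes them, which mirrors the pipeline order
the method prescribes.

**Median-area filter.** Per-object pixel areas are pooled across the whole
run (not per image — pooling is what identifies the *dataset's* dominant
class and stabilizes small images), the median $m$ is taken once on the
unfiltered distribution, and an object is kept iff its area lies in the
inclusive band $[(1-f)m, (1+f)m]$ with $f = 0.5$ by default. "Deviating by
more than 50% of the median" is the only reading under which both
exclusions make sense: merged clusters above the band, debris and
artefacts below it. The filter is a single pass — no fixed-point
re-estimation of the median after exclusion.

**Composition and background noise.** The training image keeps original
intensities on kept-object pixels and is black elsewhere, which makes mask
and image support correspond exactly. A perfectly homogeneous black
background is, however, unlike any real micrograph, and networks trained
on it generalize poorly; additive noise restores background
inhomogeneity. Defaults: Gaussian, mean 0, sd 3 on the 8-bit scale,
background-only scope (foreground stays bit-identical, preserving the
annotation signal), clipped to the bit range — so the effective background
distribution is half-truncated, a property the tests check against a
Monte-Carlo oracle rather than against the nominal sd. Noise scope is
configurable to whole-image because the choice is a modelling judgement,
not a fact about the data. Per-image seeds are derived as
`noise.seed + image index`, giving distinct but reproducible noise.

## Evaluation

Annotation quality is measured at the object level. Exact pairwise
intersections and unions give per-pair IoU; pairs with IoU ≥ t are matched
one-to-one greedily by descending IoU (ties broken by id order). At
t ≥ 0.5 a pixel can contribute to at most one above-threshold pair, so the
greedy matching provably attains the optimal assignment — the suite
confirms equality with brute-force enumeration on small random maps.
Matched pairs are TP, unmatched predictions FP, unmatched references FN;
object-level TN is undefined and carried as 0 (no formula uses it).
Precision, recall and F1 follow the standard definitions, with
zero-denominator cases defined as 0, and F1 is reported over the threshold
grid {0.50, …, 0.95}.

Mean IoU is reported in **both** conventions — over matched pairs only and
over all reference instances with unmatched ones contributing 0 — because
the gap between them is precisely the designed trade-off of this
annotation style: everything the filter kept is annotated very accurately,
while dropped nuclei count as misses only in the second convention.
`annotation_accuracy(..., restrict_to_kept = TRUE)` additionally drops
reference nuclei whose best-overlapping automatic object was excluded by
the filter, measuring "quality of what was annotated" directly.

## The synthetic generator

Real widefield data of stained nuclei are large and rarely redistributable,
so the package carries a deterministic generator whose output is a pure
function of its spec (including the seed). It renders the object classes an
annotation pipeline must cope with:

* **single nuclei** — filled ellipses, radius from a ±2 sd truncated normal
  (truncation avoids degenerate slivers and giants), axis ratio uniform in
  a configurable range, random orientation;
* **touching pairs** — two circles with centers at 0.8 (r₁+r₂), so the
  union is one connected component carrying two ground-truth labels; the
  overlap strip belongs to the first-placed member (a deterministic
  convention — some convention is needed, and this one guarantees the
  "one component, two labels" structure the watershed must split);
* **clusters** — chains of circles at 0.85 (rᵢ+rⱼ) spacing with a minimum
  separation between non-adjacent members so no instance is engulfed;
* **debris** — discs of radius 1–3 px, which by construction sit far below
  half the median single-nucleus area, so the filter must reject them.

Placement is rejection sampling of whole groups against the already-placed
member circles (bounded at 1000 attempts; a spec whose requested area
exceeds half the image, or that cannot be packed, fails with an explicit
infeasibility error). Intensities: one mean per nucleus (Gaussian around
the foreground mean — per-nucleus stain variability), per-pixel Gaussian
jitter, additive Gaussian background noise, clipped to the bit range.

Defaults were chosen once as desk-scale study conditions: 256×256 fields,
8-bit, nucleus radius 10 ± 1.5 px, axis ratio 1–1.6, foreground 180 ± 20
over background 8, background noise sd 5 (≈3% of the foreground mean, so
nuclei are comfortably separable). At these settings a default field holds
about 56 instances, which keeps whole-suite property checks (hundreds of
fields) cheap: the test suite runs fields of 192² and replicate studies at
384², and the acceptance script a 5-image dataset at 256² — sizes chosen so
each check completes in seconds while still exercising every object class.

What the generator does **not** emulate: illumination gradients,
photobleaching, shot noise, out-of-focus light, textured background, 3-D
stacks, or motion. Consequently, green tests here demonstrate the
*correctness* of the pipeline's logic and its behaviour under the stated
model — not its accuracy on any particular microscope's data, where
pre-processing choices (and the minimum peak distance, which scales with
nucleus size in pixels) must be revisited.

## Numerical and design choices worth recording

* **Coordinates** are 0-based `(row, col)` with half-open bounding boxes
  everywhere data leaves the package; one convention, stated once.
* **Label identity is not semantic**: any operation may relabel, and all
  comparisons are permutation-invariant (tested).
* **Connectivity** is 8 for components and flooding — standard for
  roundish objects; fixing it fixes every count in the suite. This is also
  why component labelling is compiled in the package rather than delegated
  (the available building blocks label 4-connected).
* **Filter band edges are inclusive**; with areas integer and the median
  generally fractional, the choice rarely matters, but determinism
  requires picking one. Even-count medians are the mean of the two central
  values.
* **Full recovery bounds.** A field is fully recoverable by the ±50% band
  only if the max/min single-nucleus area ratio stays below
  $(1+f)/(1-f) = 3$. The clean-recovery check therefore uses a
  low-variability field (radius sd 1); at the default sd 1.5 a 10-nucleus
  field regularly spans a wider ratio and the filter — correctly — trims
  its tails. This is a property of the method, not a defect: coverage is
  traded for purity.
* **Cluster geometry in purity studies.** The ±50% band argument applies
  to what the *detector* sees; a cluster only sits above the band as a
  merged component. The purity study therefore filters connected
  components of the ground-truth foreground, with touching pairs disabled
  in those fields — each pair member is itself nucleus-sized and in-band,
  so any area filter keeps it, and calling that an impurity would measure
  the label taxonomy, not the filter.
* **Timing columns** in run reports are wall-clock and excluded from all
  assertions — they exist for parity with how annotation effort is
  reported, and are hardware-dependent.
* **16-bit handling**: Otsu may run on raw 16-bit or converted 8-bit data;
  the default pipeline converts first (percentile 1–99), which is the
  robust choice for widefield data with hot pixels.

## Known limitations

* Nuclei whose area legitimately differs from the median by more than the
  band — mitotic figures, syncytia, very small nuclei — are never
  annotated; the method's premise is a dominant, low-variance size class.
* Touching nuclei are split by distance-transform geometry only; heavily
  overlapping pairs with a shallow neck may stay merged (then the merged
  object usually falls above the band and is dropped — precision is
  preserved, recall pays).
* A single global threshold assumes spatially uniform illumination;
  correct upstream or expect foreground bias.
* The greedy matcher is provably optimal only at t ≥ 0.5; below that it is
  a well-defined deterministic convention, which is why the default grid
  starts at 0.5.
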