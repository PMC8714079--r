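---
title: "Quantification methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoquant)
```

This vignette documents the measurement models implemented in
`embryoquant`, the parameters that matter, the numerical conventions, and
the choices made where the underlying procedures left room for
interpretation. The recordings it targets are spinning-disc confocal time
series of one-cell *C. elegans* embryos: 10–12 z-sections of 0.8 µm taken
every 10 s, one or two channels recorded simultaneously, intensities
treated as unitless camera counts (8- or 16-bit).

## Image model and conventions

Frames are numeric matrices (row = y, column = x) with 1-based indices;
rectangular ROIs are inclusive (`x0`, `y0`, `width`, `height`), and frame
indices are 1-based throughout, so the metaphase frame of an embryo with
anaphase onset at frame *k* is frame *k − 1* and an onset at frame 1 is an
error (no prior frame exists). Max projections serve segmentation and
per-pixel statistics; sum projections serve total-intensity measurement,
accumulated in double precision and never clipped to the input bit depth —
total intensity must be conserved across slices. Channel registration is
assumed (simultaneous acquisition); z-drift during acquisition is ignored,
stacks being treated as complete per timepoint. TIFF files store one page
per (T, Z, C) combination with the order declared explicitly; round trips
are bit-exact for 8- and 16-bit data.

## Histogram thresholding

Both auto-thresholds operate on a 256-bin histogram spanning the data
minimum to maximum (for full-range 8-bit data the bins coincide with the
integer levels). This reproduces the 8-bit histogram convention of the
interactive tool these steps come from, keeps exhaustive search over all
splits cheap even for 16-bit input, and makes the thresholds invariant
under histogram duplication. Conventions:

* Otsu maximizes the between-class variance
  $\omega_0\omega_1(\mu_0-\mu_1)^2$; maximum entropy (Kapur–Sahoo–Wong)
  maximizes the sum of the Shannon entropies of the renormalized histogram
  on each side of the split.
* Candidate splits are restricted to those with mass on both sides. For
  the entropy criterion this matters: counting an empty side as zero
  entropy would let a split below the lowest occupied bin win on a
  two-delta histogram, which is not what the reference tool does.
* Ties break toward the smallest split, and foreground is "strictly above
  the background bins": for integer data on unit bins, pixel > threshold.
* A histogram with fewer than two occupied bins is degenerate and errors.

Connected components use 8-connectivity (the particle-analysis default);
"expand by *k* pixels in each direction" is square (Chebyshev) dilation by
a $(2k+1)\times(2k+1)$ element, clipped at image borders. The circular
mean filter (radius 2 px for segmentation smoothing) averages over
in-bounds neighbours only, so it never moves values outside the input
range. Contrast stretching is linear min–max and is applied **only** to
segmentation copies, never to pixels being quantified; because the stretch
is monotone and histogram bins follow the data range, entropy thresholds
select the same pixel set on raw and stretched data (asserted as a test).

## Metaphase-plate quantification

The plate ROI comes from the max-projected chromatin channel at the
metaphase frame via maximum-entropy thresholding; when the mask has several
components the largest is taken unless a seed point is supplied. The
background ring is the 5-px Chebyshev dilation of the *mask-derived* ROI
minus the ROI itself — a bounding-box ring would include plate-adjacent
signal for elongated plates, and the dilated mask is what "expanded in each
direction" means for a free-form ROI. The correction

$$\bar b = \frac{T_\text{exp} - T_\text{roi}}{A_\text{exp} - A_\text{roi}},
\qquad T_\text{corr} = T_\text{roi} - A_\text{roi}\,\bar b$$

is exact for a constant offset over the frame (the offset cancels
algebraically, asserted to machine precision) and exact on noise-free
plates. Negative corrected totals are reported with a flag, never clipped:
clipping would bias group means upward. Normalization divides by the
control mean, making the control average exactly 1.

## Condensation parameter

Within the 21×21 px ROI centred on the paternal pronucleus, values are
min–max rescaled to [0, 255] and the parameter is the fraction of pixels
**strictly below** 102 (0.4 × 255; boundary pixels at exactly 102 count as
not-below). Rescaled values are kept as reals — re-binning to integers
would only add quantization error. The rescaling makes the statistic
invariant under positive affine transforms of the raw intensities, which
is what removes photobleaching and gain differences; this invariance is
asserted over random ROIs. A constant ROI returns 0: uniform nucleoplasm
is the diffuse limit with no visible condensation.

Centring uses a filtered segmentation copy (contrast stretch → mean filter
r = 2 → Otsu → centroid of the component nearest the seed), while the
parameter itself is always computed on the **unfiltered** max projection:
filtering would alter the very pixel distribution the statistic
summarizes, and the min–max rescale already removes gain effects. Both
seeded-centroid and fixed user-supplied centres are supported, covering
either way the original centring may have been done. If segmentation fails
in a frame the previous centre is carried forward for at most 2 consecutive
frames (with a message); longer losses error. Curves are aligned with NEB
at *t* = 0 (10 s cadence), aggregated per timepoint as mean and sample
s.d. (n = 1 timepoints report s.d. 0), and smoothed for display by
degree-1 local regression with tricube weights over the
$\lceil 0.4\,n\rceil$ nearest points — exact on linear data, implemented
directly from that definition and cross-checked against the reference
local-regression implementation in the tests.

## Other time-course metrics

Nuclear time courses use max projections (acquired stacks need not cover
the whole nuclear volume, so sum projections would depend on stack
placement): corrected mean = (total maternal + paternal − total area ×
cytoplasm mean) / total area, with a 25×25 px cytoplasm reference region.
Manual annotations (pole coordinates, NEB/anaphase frames, FRAP border,
cytoplasm region) are consumed as data, not re-automated — they were scored
by eye in the workflow this package reproduces, and automating them would
change the measurement. Pole distances are Euclidean on possibly
fractional coordinates times the pixel size; FRAP profiles average the 10
transverse pixels at each of 150 positions along the plate axis and are
reported raw (no pre-bleach normalization), averaged positionwise across
replicates with s.d. Lethality is the unhatched fraction per replicate,
summarized as the per-condition mean over biological replicates.

## Statistical decision tree

The tree is a pure function of the per-group Shapiro–Wilk p-values, the
sample-variance ratio and the group count: all groups normal (every
p ≥ 0.05) → Student's *t* (2 groups, max/min variance ratio < 3), Welch's
*t* (2 groups otherwise), or ANOVA + Tukey–Kramer (> 2 groups); any
failure → Kruskal–Wallis + Dunn with Benjamini–Hochberg adjustment. One
sentence in the source description printed the Shapiro–Wilk inequality
inverted; the conventional reading (p ≥ 0.05 ⇒ treat as normal) is
implemented. Variance similarity is judged on the same normalized values
fed to the test. Tukey–Kramer uses the studentized-range distribution with
the unequal-n correction; Dunn's z uses tie-corrected rank variance. The
full pipeline's type-I error is calibrated by simulation (≈5 % at
α = 0.05 over 2000 null replicates in the acceptance suite).

## Synthetic data: what it emulates, and what it does not

Generators are pure functions of their parameters and seed (bit-identical
for equal seeds; the caller's RNG stream is restored). The camera model is
Poisson shot noise on expected counts plus Gaussian read noise (default
s.d. 5 counts), rounded and clamped to 16 bits; optics enter only through
the Gaussian widths of rendered structures. Defaults are chosen to be
realistic for EMCCD spinning-disc imaging of these embryos: 256×256 frames
(512×512 available via `frame_size`), 10 s cadence, cytoplasmic background
100 counts, diffuse chromatin peak 600 counts, condensed foci ~2000
counts, metaphase plates of 400 px at 2000 over 200 counts,
embryo-to-embryo variability lognormal with CV 0.12. The condensing
nucleus ramps a compaction index linearly from an onset 24 frames (240 s)
before NEB at `compaction_rate` per frame (default 0.04, i.e. full
compaction roughly at NEB), fading the diffuse cloud and sharpening six
foci in proportion, with a small random-walk drift of the centre.

What passing tests on these images show is that the *measurement
machinery* is correct and well calibrated — projections, thresholds, ring
correction, the statistic's invariances, the decision tree's operating
characteristics. They do not show that real chromatin looks like six
Gaussian foci: the generators omit 3-D PSF structure, spectral
bleed-through, focus drift, neighbouring nuclei and polar bodies, and any
chromosome mechanics. Absolute condensation-parameter baselines on real
data will differ from the synthetic ones; the package's claims are about
exactness, invariance, ordering and calibration, not about reproducing
biological magnitudes.

## Problem sizes and runtime choices

The test and acceptance runs use desk-scale sizes chosen as the package's
own defaults: 256×256 frames, 40–60-frame series, 10 paired seeds for
rate-ordering, 400–1000 random histograms for exhaustive-search
equivalence, 1000/2000 replicates for power and type-I calibration, 20
embryos per group for end-to-end recovery. These sizes give simulation
standard errors comfortably inside the asserted bands (e.g. ±1 % on a 5 %
rejection rate at 2000 replicates).

## Known limitations

* No deconvolution, flat-field correction, registration or drift
  correction; inputs are assumed pre-processed to that extent.
* Segmentation is 2-D on projections; no watershed splitting of touching
  nuclei, so closely apposed pronuclei may merge into one component (the
  seed-point mode mitigates this).
* The TIFF reader handles the declared (T, Z, C, Y, X) page layouts only;
  it does not parse OME-XML metadata.
* FRAP analysis is descriptive (profiles only); no kinetic model is
  fitted, as the motivating experiments showed no recovery.
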