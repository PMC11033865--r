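---
title: "Radiality filtering of fluorescent puncta: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiality filtering of fluorescent puncta: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Images of tissue and cells carry three components: the diffraction-limited
signal one wants to detect (*puncta* — approximately 2D Gaussian spots of
width $\sigma \approx 1.2$–$1.4$ px on a well-sampled camera), spatially
structured autofluorescence, and detector noise. Conventional spot
detectors threshold an enhanced image and therefore label bright
autofluorescent structure as puncta: in structured samples most detections
can be false positives. This package implements a *radiality* filter: every
candidate is scored by how much it looks like a radially symmetric
point-spread function, and a decision boundary learned from negative-control
images (samples in which every detection is by construction a false
positive) rejects the rest.

## The two radiality metrics

Both metrics are evaluated on a ring of pixels at Chebyshev distance $r$
from the candidate's local maximum in the **raw** image (the perimeter of
the $(2r+1)\times(2r+1)$ window; $8r$ pixels, 16 at the default $r = 2$):

* **Flatness** — the mean ring intensity over the center intensity,
  $\frac{1}{n}\sum_k I_k / I_{\max}$. A true punctum puts the decaying flank
  of the PSF on the ring, so its flatness is low; broad autofluorescent
  features have flatness near 1. Flatness is invariant under multiplicative
  rescaling but *not* under additive offsets — the background level enters
  deliberately, since contrast against background is part of what makes a
  spot detectable.
* **Integrated gradient** — the sum of gradient magnitudes
  $\sum_k G^k_{\mathrm{pixel}}$ over the same ring, with
  $G = \sqrt{G_x^2 + G_y^2}$ from per-pixel gradients of the raw image. A
  radially symmetric punctum puts the steepest part of the PSF on the ring;
  single-pixel noise spikes (whose gradient support does not reach the
  ring) and smooth structure both score low. The metric is homogeneous of
  degree 1 and offset-invariant.

The pairing is what separates: sharp-but-extended objects (true puncta)
are the only candidates that are simultaneously in the low-flatness and
high-gradient corner. A noise spike is sharp but not extended; a blob is
extended but not sharp. Numerically, both orderings that this premise
relies on are verified against brute-force double-loop references in the
test suite. One ordering the package does *not* claim: an elongated
Gaussian of equal peak actually has a slightly *higher* integrated gradient
than the symmetric one (its slower off-axis decay raises ring intensities),
so the gradient metric's discriminating power is against scattered or
ring-poor intensity distributions, while flatness handles elongation and
broadening.

### Ring, gradient and tie conventions

* The ring is the Chebyshev (square-perimeter) ring. The choice of metric
  for "2 px away" is a convention; the Chebyshev ring is
  orientation-symmetric under the 90° symmetries of the pixel grid and has
  a fixed pixel count ($8r$). The radius defaults to 2 px — the nearest
  integer to the PSF half-width at half-maximum for optimally sampled
  single-molecule data — and is configurable (`ring_radius`) for other
  samplings.
* Gradients use central differences in the interior and one-sided
  differences on the borders: the minimal stencil that is exact for affine
  images. A Sobel-type stencil could be substituted without changing any
  interface.
* The candidate's center is the argmax of the raw image over the candidate
  component; ties break to the lexicographically lowest `(row, col)`, so
  detection is deterministic.
* A candidate whose ring leaves the image is discarded (counted in
  `n_edge_dropped`); a candidate with non-positive center intensity has
  undefined flatness and is discarded likewise.

## The detection pipeline

`detect_puncta()` runs: (1) high-pass filtering — the image minus its
$\sigma = 1.4$ px Gaussian blur — which removes structure broader than a
couple of PSF widths; (2) Laplacian-of-Gaussian enhancement at
$\sigma = 2$ px, negated so blobs become maxima (the LoG kernel is
zero-sum, so constants map exactly to zero); (3) a global threshold keeping
the top 5% brightest enhanced pixels (ties at the percentile value are all
kept; a constant enhanced image keeps everything and warns); (4) 8-connected
component labeling and per-candidate measurement on the raw image;
(5) optionally, the decision boundary. Filters use reflect padding — edge
behavior changes threshold statistics, so it is fixed and stated. All
candidates are returned with a `passed_filter` flag rather than dropping
rejects, so the filter is auditable.

Local background is the mean raw intensity over a Chebyshev annulus
(default radii 3–5 px) around the peak, clipped to the image; the summed
spot intensity is the component sum minus background times area. This is
the fast per-spot estimator used in place of Gaussian fitting; on
simulated spots with known mass it is accurate to a few percent, limited
mainly by PSF tails inside the annulus.

## Learning the decision boundary

`train_boundary()` pools the two metrics over unfiltered detections in
negative-control images and places independent percentile cutoffs in the
true-positive directions: the lower tail of flatness and the upper tail of
integrated gradient, by default the 5% tail in each dimension separately.
Percentiles interpolate linearly between order statistics (type 7), stated
for reproducibility. The combination rule defaults to `"and"` — both
criteria must indicate a symmetric punctum — because each tail alone admits
a characteristic failure mode (noise spikes pass the flatness tail, steep
structure edges pass the gradient tail); `"or"` is available. Training
demands at least 20 pooled candidates and non-degenerate metric
distributions. By construction, re-applying an `"and"` boundary to its own
training data retains at most the training percentile.

## The scene simulator

`scene_series_by_cnr()` and its parts generate ground-truthed scenes:
Gaussian puncta of equal amplitude (grid or uniform-random placement with a
$6\sigma$ minimum separation), Poisson shot noise on the punctum image,
large irregular aggregates inserted by the distance-transform sigmoid, and
a structured background, composed by exact pixel-wise addition (the stored
components always sum to the stored image). Per punctum, a binary mask —
Otsu's threshold of the isolated rendered spot — records the covered
pixels; the true background is the background mean over that mask and the
true contrast-to-noise ratio is
$\mathrm{CNR} = (S_A - \bar S_B) / \sigma_B$ with the sample standard
deviation over the mask.

Choices that were genuinely open, and how they were decided:

* **Background model.** The background is a smooth autofluorescence level
  (`mean_level` 100 photons, relative contrast 0.4, correlation scale 8 px)
  *Poisson-sampled*, plus Gaussian read noise (sd 3 photons), clipped at
  zero. Shot-noise sampling of the level is essential: photon counting
  forces the pixel noise to scale as the square root of the local level,
  and any flat noise floor plants unphysically sharp features in dim
  regions — measurably distorting the negative-control flatness
  distribution. The levels are typical of autofluorescent tissue at
  moderate excitation; the contrast and scale put strong, smooth structure
  into the field without making it punctate.
* **Aggregate inserts.** ROIs come from a programmatic generator (smooth
  random field thresholded into an irregular blob, amplitude ~500 photons
  over an 80×80 crop) standing in for a manually cropped aggregate
  library; any user-supplied TIFF crop works through `prepare_aggregate()`.
  The correction sigmoid is $c = 2/(1+\exp(d/a))$ with $a = 10$ px — equal
  to 1 on the aggregate (distance 0) and decaying with length scale $a$ —
  which satisfies its purpose of keeping the aggregate signal while
  suppressing the residual background of the crop; the exact printed form
  of the published sigmoid is not recoverable, so this form is documented
  as inferred. Aggregate surface texture is band-limited at 3 px,
  deliberately *broader* than the PSF: texture at exactly the PSF scale
  would constitute genuine unlabeled puncta and corrupt the ground truth.
* **Overlap deletion.** Puncta whose masks intersect an aggregate
  footprint are deleted from the truth table *after* composition; their
  photons remain in the image. This is the interpretation that keeps the
  image physical (photons cannot be un-emitted); it slightly penalizes
  measured precision, since detections of those spots count as false
  positives.
* **CNR calibration.** Scene series solve the punctum amplitude by
  bisection of the noiseless render against the requested mean CNR
  (tolerance 5%, typically converged to 0.5%); positions, background and
  aggregates are shared across the series so only amplitude and the
  per-scene Poisson draw vary. Puncta on locally constant background
  (zero-clipped dead zones) have undefined CNR; they stay in the truth
  table with `cnr_true = NA` and are excluded from the calibration mean.

What the generator does *not* emulate: camera-specific excess noise
(EMCCD), depth-dependent PSF shape, out-of-focus light, multi-scale or
punctate autofluorescence (e.g. lipofuscin granules at the PSF scale), and
spatial correlation between aggregates and background. Passing tests on
these scenes therefore show that the pipeline behaves as designed under
shot-noise-limited structured background — not that it rejects punctate
autofluorescence, which is information radiality alone cannot provide.

## Benchmarking

`match_detections()` pairs detections to ground truth greedily by ascending
distance, one-to-one, within a 2 px radius (the matching rule is a
convention; the radius is configurable), and
`jaccard_index()` / `precision()` / `sensitivity()` score the result.
`cnr_sweep_report()` runs any detector — a position-list callable, so
third-party detectors plug in — across a CNR series. The validation suite
uses the published scene design at desk scale: a 1200×1200 field, 400
puncta, 4 large aggregates, CNR swept over 2–12, with the boundary trained
on three matched puncta-free backgrounds; the acceptance tests assert
Jaccard ≥ 0.90 at CNR ≥ 8, monotone improvement with CNR, and a >100-fold
reduction of false positives on puncta-free fields.

## Colocalization statistics

For a field of view with a binary cell mask, the inside-cell ratio (ICR)
is the fraction of puncta whose rounded position lands on a mask pixel;
the colocalization likelihood is ICR divided by the mask area fraction —
above 1 means enrichment inside cells. The null is complete spatial
randomness (CSR): positions uniform over *all* pixels (not mask-excluded;
that is the definition of the null), whose likelihood converges to 1 and
whose sample sd over repeats is the per-FOV error bound. Error bounds
shrink as $n^{-1/2}$ in the punctum count. Fields with no detections or
degenerate masks are skipped and counted, never imputed; `aggregate_fovs()`
reports the across-FOV mean and sd of both the likelihood and the error
bound (the within-FOV sd is the error bound; the across-FOV sd is reported
separately, so both readings of "the error bound's sd" are available).

## Camera calibration

`estimate_calibration()` implements per-pixel photon-transfer calibration:
the offset is the dark-stack mean; across illumination levels the
shot-noise variance grows linearly with the offset-subtracted mean, so an
ordinary least-squares fit per pixel (with intercept — the intercept
absorbs read noise, which is why it is fitted rather than forced through
zero) gives a slope in counts per photoelectron, and the gain is its
reciprocal, in photoelectrons per count (multiply offset-subtracted counts
by the gain to get photons). Offset subtraction happens before the fit.
Pixels with non-positive slope are flagged invalid and propagate as `NA`
through `counts_to_photons()`. The validation uses the standard series
design of seven illumination levels at 1000 frames each; gain recovery is
within 5% per pixel at that depth.

## Problem sizes and numerical conventions

The test and acceptance workloads use 1200×1200 scenes for the detection
benchmark, 1024×1024 masks with 10⁴ puncta and 100 repeats for the CSR
null, 10⁶ pixels for the Poisson mean–variance check, and a 16×16-pixel
camera over 7×1000 frames for calibration — sizes chosen so each check is
statistically decisive at desk scale. All stochastic steps take explicit
seeds; child seeds derive deterministically from the master seed, and
seeded runs are bit-reproducible, including CLI file outputs. Quantiles
everywhere are type-7 (linear interpolation); standard deviations are
sample (n−1); threshold ties are kept; candidate and matching order are
deterministic.

## Known limitations

Flatness depends on the local background level, so very bright smooth
background depresses the contrast of weak puncta and the boundary can
reject true spots sitting on it — at CNR ≈ 8 this costs a few percent
sensitivity on structured scenes. The global top-5% threshold lets bright
aggregates consume threshold budget, which can push weak puncta below the
cut in their vicinity. Subpixel localization, anisotropic PSFs, per-tile
thresholds for very large fields, and learned nonlinear decision
boundaries are out of scope.
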