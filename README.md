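# rasp — radiality-based detection and filtering of fluorescent puncta

`rasp` detects diffraction-limited fluorescent spots (*puncta*) in
microscopy images whose background is structured — tissue
autofluorescence, cellular debris, large protein aggregates — rather than
flat. It is written for quantitative-microscopy work such as counting
protein aggregates in stained tissue sections or scoring spot–cell
colocalization in high-throughput imaging, where conventional spot
detectors drown the signal in false positives from bright background
structure.

## The method

Candidates come from a standard enhancement pipeline: high-pass filtering
(image minus its σ = 1.4 px Gaussian blur), negated Laplacian-of-Gaussian
enhancement (σ = 2 px), thresholding at the top 5% brightest enhanced
pixels, and 8-connected labeling. Each candidate is then scored on a ring
of pixels at radius 2 from its local maximum in the **raw** image by two
radiality metrics:

* **flatness** `(1/n) Σₖ Iₖ / I_max` — mean ring intensity over the peak
  intensity; *low* for a sharply peaked punctum, near 1 for broad
  structure;
* **integrated gradient** `Σₖ Gₖ`, `G = √(Gx² + Gy²)` — the summed
  gradient magnitude on the ring; *high* for a radially symmetric spot,
  low for noise spikes and smooth background.

False positives are rejected by a decision boundary learned from
negative-control images (e.g. secondary-antibody-only stains), in which
every detection is assumed false: the boundary takes the 5% tails of the
pooled metric distributions — the lower flatness tail and the upper
integrated-gradient tail — and by default accepts only candidates passing
*both* cuts. Only sharp **and** extended objects survive, which is exactly
the PSF-shaped signal.

The package also provides the supporting instruments: a ground-truthed
scene simulator (Gaussian puncta with Poisson noise, large-aggregate
inserts via a distance-transform sigmoid, Poisson-sampled structured
backgrounds, amplitude calibration to requested contrast-to-noise ratios),
detection benchmarking (greedy one-to-one matching, Jaccard index,
precision, sensitivity, CNR per `(S_A − S̄_B)/σ_B`), per-pixel sCMOS
photon-transfer calibration (offset from dark frames, gain from the
variance-vs-mean slope), and cell–punctum colocalization statistics with a
complete-spatial-randomness (CSR) reference.

## Worked example

Train a boundary on puncta-free backgrounds, simulate a scene with known
ground truth at CNR 8.7, detect, filter, and score:

```r
library(rasp)

negatives <- lapply(1:2, function(i) synth_background(c(512, 512), rng_seed = i))
boundary  <- train_boundary(negatives, percentile = 5, mode = "and")
boundary
#> rasp decision boundary
#>   accept if flatness <= 0.751411 AND integrated gradient >= 231.06
#>   trained at percentile 5 on 5831 candidates from 2 image(s)

scenes <- scene_series_by_cnr(c(512, 512), cnr_values = 8.7, n_puncta = 64,
                              n_aggregates = 1, rng_seed = 42)
scene <- scenes[[1]]
scene
#> rasp scene: 512x512 px, 64 truth puncta (0 deleted under aggregates)
#>   mean true CNR 8.68, mean true background 99.9 photons

detections <- detect_puncta(scene$image, boundary = boundary)
detections
#> rasp detections: 2626 candidate(s), 62 passed filter
#>   dropped: 83 edge, 0 area, 0 non-positive peak

m <- match_detections(cbind(scene$truth$y0, scene$truth$x0), detections,
                      match_radius = 2)
m
#> rasp match (radius 2 px): tp 61, fp 1, fn 3; jaccard 0.9385
c(precision = precision(m), sensitivity = sensitivity(m))
#> precision 0.984, sensitivity 0.953
```

Of 2626 raw candidates on this structured scene, the radiality boundary
keeps 62; 61 of them sit within 2 px of a true punctum. The unfiltered
candidate set has precision 0.024 on the same scene — the filter trades a
~5% sensitivity loss for a ~40-fold precision gain.

## Command line

A thin CLI wraps the same functions (installed under `exec/rasp`):

```sh
rasp train-boundary --input negatives/ --output boundary.json
rasp detect --input images/ --boundary boundary.json --output detections/
rasp simulate --rows 1200 --cols 1200 --n-puncta 400 --cnr 2,4,6,8,10,12 --seed 1
rasp evaluate --truth scene_truth.csv --detections scene_detections.csv
rasp colocalize --detections detections/ --mask cells.tif
rasp calibrate --dark dark.tif --levels l1.tif,l2.tif,...
```

Every run writes its resolved configuration (seeds included) next to its
outputs; fixed-seed runs are bit-reproducible. Exit codes: 0 success,
2 validation error, 3 I/O error.

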