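---
title: "Segmentation-assisted flattening of AFM height images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-assisted flattening of AFM height images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmflatten)
```

## The problem

An AFM reconstructs topography point by point while two piezo stages drift
relative to each other. The resulting height image is the sample relief
plus a slowly varying background: plane tilt, quadratic/cubic bow,
low-frequency undulations, and per-scan-line offsets from drift that
accumulates along the slow axis (each line takes ~1 s; a frame takes
minutes, so within a line the drift is far smaller than between lines).
Flattening estimates this background and subtracts it. The catch is that
the estimate must come from *background* pixels only: a polynomial fitted
through a protruding nanobubble is pulled upward and, once subtracted,
digs a dark stripe around the feature. Manual rectangular masks are the
usual workaround; this package automates mask extraction and couples it to
several background models.

Throughout, a height image is a numeric matrix in nanometres with a pixel
size; **each matrix row is one scan line** (fast axis = column index), and
a `fast_axis` flag plus `transpose_image()` cover data stored the other
way. Heights are always nm; there is no unit autodetection.

## Step 1: foreground extraction

`segment_features()` runs, per polarity:

1. **Adaptive thresholding.** A pixel is foreground if it exceeds its
   local mean (box window `window_px`, edge-replicated) by `offset_nm`.
   The local mean tracks any smooth background, which makes the test
   insensitive to tilt and bow; `offset_nm` (default 1 nm) is the minimum
   prominence of a feature and should sit a few noise standard deviations
   above the floor. The exact thresholding rule is not prescribed by the
   contour-expansion literature; the local-mean form was chosen because it
   is standard, has one interpretable parameter, and is testable against a
   brute-force oracle.
2. **Cleanup.** 3×3 morphological opening plus a minimum-area filter
   (`min_area_px`, default 20 px²) so isolated noise pixels do not seed
   contours.
3. **Contour expansion.** The boundary of each surviving 8-connected
   component, traced and resampled to uniform spacing, seeds a greedy
   active contour. Each point examines its `neighborhood`×`neighborhood`
   candidate moves and takes the move minimising
   `alpha*E_cont + beta*E_curv - gamma*|grad| - pressure*E_press`, every
   term min–max normalised over the candidate set. `E_cont` penalises
   deviation from the mean inter-point spacing, `E_curv` is the discrete
   second difference, the gradient magnitude is computed on a
   Gaussian-smoothed image (`gradient_sigma_px`), and `E_press` is the
   outward component of the move (outward = away from the contour
   centroid). The contour is resampled every `resample_every` iterations
   and stops when fewer than `move_tol` of its points moved.
4. **Rasterisation and filtering.** Final polygons are filled with the
   even-odd rule (boundary pixels included — exclusion should err on the
   generous side). Components whose interior mean does not rise above the
   mean of their immediate surrounding band are discarded: the local mean
   under an opposite-polarity feature is depressed, so thresholding also
   fires on the flat ring *around* a pit, and that ring — once filled —
   encloses the low feature and fails this convexity check.

Concave features are segmented by running the identical convex machinery
on the complement image `max(I) - I`, which makes the polarity-duality
property (`concave(I) == convex(complement(I))`) exact by construction.

### Parameter defaults

The contour-expansion literature does not publish default energy weights,
so the defaults here (`alpha = beta = 0.4`, `gamma = 1.2`,
`pressure = 0.35`, `gradient_sigma_px = 1`, 3×3 neighbourhood) were
calibrated once on synthetic cap scenes and then frozen. Two behaviours
anchor them: with the defaults, a deliberately under-estimating seed
contour on a 14 px cap expands ~4× in area and locks onto the gradient
ridge; raising `alpha`/`beta` several-fold suppresses the expansion — the
documented under-estimation behaviour of stiff contours. The gradient
smoothing sigma matters most: heavy smoothing (σ = 2) pulls the apparent
gradient ridge of a smooth-shouldered cap several pixels inside its true
footprint, while σ = 1 keeps the ridge near the rim at the noise levels
the generator produces (≤ 0.5 nm). Because the detected ridge still sits
slightly inside the relief support, the final mask is dilated by 1 px by
default (`dilate_px`); flattening callers typically dilate 2 px.

## Step 2: background subtraction

All methods share one contract: estimate a baseline from background
pixels, evaluate it at *every* pixel (the baseline must be defined under
features so it can be subtracted there), subtract. `flattened` and
`background_est` are stored so that
`input - flattened == background_est` holds bitwise; the additive identity
`flattened + background_est == input` then holds to double rounding
(≲ 1e-9 nm), which is the strongest decomposition guarantee IEEE
arithmetic permits for independently rounded fields.

* `flatten_lines()` — order-3 polynomial per scan line over background
  samples (all samples reproduces classic *direct* flattening and its
  dark stripes). Fitting coordinates are normalised to [−1, 1] per line
  before building the Vandermonde system; this keeps degree-3 systems
  well conditioned and avoids the oscillation problems that push people
  toward ever-higher orders.
* `flatten_surface()` — one total-degree-3 surface (10 monomials). A
  single surface cannot represent per-row drift, which is why line
  fitting usually wins on real scans; the surface variant is kept for
  smooth tilt/bow-only images.
* `swcf()`/`swsf()` — sliding-window curve/surface fitting. A window
  (default stride 1) is anchored at every position fully inside the
  line/image (the last anchor is always included, so end pixels are
  covered by earlier windows rather than by shrinking windows, which
  would change the degrees of freedom mid-line); each window fits order 3
  to its background samples, skipping windows with fewer than order + 2
  of them (or a rank-deficient design); every pixel averages the
  evaluations of all windows covering it, with uniform weights. Pixels
  covered by no valid window are interpolated from covered neighbours.
  Small windows track complex backgrounds; as the window grows the
  method degrades gracefully toward the single-polynomial fit, which is
  the window-size monotonicity property the tests assert.

Numerical and degenerate-input choices:

* A line is fitted at full order only if its background samples number at
  least order + 2 **and** span at least half the line — a cubic fitted to
  points clustered at one end extrapolates catastrophically. Other lines
  get their baseline interpolated per pixel from the nearest fitted lines
  (linear between, least-squares linear extrapolation over the nearest
  ≤ 8 lines beyond the ends) and are then re-anchored by their own mean
  background residual, so a per-row drift offset survives even on lines
  that are almost entirely foreground.
* Ties in the greedy contour move go to "stay put" (the zero offset is
  evaluated first); segmentation and flattening contain no randomness, so
  identical inputs give identical outputs.

## The two-pass pipeline

`two_pass_segment()` segments the raw image, flattens with the pass-1 mask
(dilated 2 px), and segments again. Two pass-1 component classes are
excluded from the *fitting* mask (they remain in the reported pass-1
mask): components larger than `max_mask_frac` (10%) of the image, and
components confined to the border band of half a threshold window, where
edge-replicated local means are biased — both are almost surely
mis-segmented background whose exclusion would starve the fits.

## The synthetic-scene generator

`make_background()` sums plane tilt (nm/px), polynomial bow (coefficients
in normalised coordinates), low-frequency sinusoids (periods > 4 px),
per-row random-walk drift (constant within a row, step SD in nm) and
Gaussian pixel noise; all stochastic components are seeded and scenes are
bit-reproducible. Features are spherical caps
`z(rho) = h (1 - rho^2/r^2) s(rho)` with a raised-cosine shoulder `s` over
the outer 10% of the footprint radius — a pure cap has a gradient
discontinuity at the rim that would make edge detection unrealistically
easy — pits (the same shape subtracted), and square-pit calibration
gratings. The ground-truth mask is exactly the support of the relief.

What the generator does *not* emulate: tip–sample convolution, feedback
overshoot, scanner hysteresis/creep nonlinearity, or correlated 1/f noise.
Passing tests therefore demonstrate correct recovery of additively
composed backgrounds under exact or self-detected masks, not robustness to
every instrumental artifact of a physical AFM.

## Evaluation fixtures and problem sizes

The test suite runs everything on generated scenes: 96–192 px images for
unit tests; a 256 × 256 grating (pitch 64 px, pit width 26 px, 180 nm
depth) for the morphometry check, with the tilt gradient set so the raw
one-pitch cross-section depth overestimates the nominal by 8%; a
256 × 256 crossed-sinusoid scene for window-size monotonicity at stride 1;
and a ten-scene suite of 192 × 192 images with 20 caps each (radius
6–11 px, height 8–25 nm, strong tilt, moderate bow, drift step 0.4 nm,
noise 0.3 nm) for the two-pass comparison — conditions under which the
raw-image pass reliably commits over- or under-segmentation errors while
remaining recoverable. These sizes were chosen as the smallest scenes that
exercise each behaviour convincingly.

Depth is reported as the literal max-minus-min of a cross-section — the
standard grating read-out, deliberately sensitive to residual tilt;
`feature_depth_median()` (median plateau minus median floor) is provided
as a robust alternative but is not used in the headline comparison.
Residual statistics remove the global mean before the RMS because
polynomial subtraction is only defined up to the constant absorbed into
the background model.

## Known limitations

* The detected boundary is the gradient ridge; for features whose relief
  decays smoothly to zero the outermost low-slope fringe is attributed to
  the background unless covered by the default dilation.
* Features wider than a sliding window leave the under-feature baseline
  to interpolation; keep windows larger than the largest masked feature
  when apex heights matter.
* `feature_depth()` on noisy profiles is biased upward by the extreme
  statistics of max-minus-min; use the median variant when that matters.
* The CLI reads whole images into memory; scans beyond ~4k × 4k px should
  be processed tiled, which the package does not do.
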