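---
title: "Methods: constrained MCR-ALS unmixing of FTIR image multisets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained MCR-ALS unmixing of FTIR image multisets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsimcr)
```

## The problem and the model

Mid-infrared absorbance images of thin plant-tissue sections mix the
signatures of several constituents in every pixel: at a 3 x 3 um^2 pixel a
softwood section contains cell-wall polysaccharides, lignin, extractive
deposits and, in empty lumina, only the substrate. By the Beer-Lambert law
the absorbance cube, unfolded to a pixels-by-wavenumbers matrix `D`, follows
a bilinear model

    D = C %*% S_t + E

where each row of `S_t` (k x channels) is the pure spectrum of one
constituent, each column of `C` (pixels x k) is its concentration over the
pixels, and `E` collects noise and model error. Multivariate curve
resolution by alternating least squares (MCR-ALS) estimates `C` and `S_t`
under physically motivated constraints. When several images share the same
spectral axis — here, sections cut across a series of annual rings from
sapwood to heartwood — their unfolded matrices are stacked row-wise into one
*multiset* and factored jointly: a single `S_t` for all images, and one `C`
block per image that refolds into that image's distribution maps.

The quality of a fit is summarized by the lack of fit,
`LOF = 100 * sqrt(sum(E^2) / sum(D^2))`, the percent unexplained signal.

## Pipeline

`resolve_images()` chains the steps a practitioner would run by hand:

1. **Window truncation** (`truncate_range`): only 1200–1750 cm^-1 is kept;
   outside this window real wood sections of ~10 um thickness oversaturate.
2. **AsLS baseline correction** (`correct_image`): asymmetric least squares
   removes the broad Mie-type scatter oscillation (below).
3. **Multiset augmentation** (`augment`): row-major unfolds, stacked in ring
   order, with pixel provenance recorded; invalid (saturated) pixels never
   enter the matrix, and an entirely invalid image is dropped with a warning.
4. **Rank selection** (`svd_scree` + `select_rank`): the number of
   components is read from the singular-value scree.
5. **SIMPLISMA initial estimates** (`simplisma_init`): the k purest pixel
   spectra.
6. **Preliminary unconstrained fit** + **presence estimation**
   (`estimate_presence`): automates the map inspection that identifies
   components absent from some rings.
7. **Constrained fit** (`mcr_als_fit` with `correspondence`): the final
   model, with absent components pinned to exactly zero in their rings.

## AsLS baseline correction

The baseline `z` minimizes `sum(w_i * (y_i - z_i)^2) + lam * sum((d2 z)^2)`
with weights `w_i = p` where `y_i > z_i` and `1 - p` otherwise, iterated to
a stable weight vector (Whittaker smoothing with asymmetric weights). Each
inner step is solved exactly by a banded Cholesky factorization of the
pentadiagonal normal matrix (O(n) per spectrum, C++). The second-difference
operator acts on the index grid; after truncation the axis is uniform, so
this differs from the physical cm^-1 grid only by a constant factor absorbed
into `lam`.

Defaults are `lam = 1e5`, `p = 0.001`, `max_iter = 10` — conventional
magnitudes for a few-hundred-channel FTIR window; both are exposed in
`asls_params()`. Two properties of the method matter for interpretation and
are asserted by the tests at honestly measured bounds rather than idealized
ones:

* AsLS tracks only oscillations that are *slow* relative to the smoothness
  scale set by `lam`. At `lam = 1e5` on a 2 cm^-1 grid the full-tracking
  regime starts around periods of 4000 cm^-1; an oscillation with a period
  of ~1000 cm^-1 (as in the synthetic scenes) is removed only in bulk
  (offset and tilt), leaving a residual of roughly a quarter of its
  amplitude. The default scene therefore uses a small amplitude (0.02 a.u.,
  ~3% of peak absorbance), consistent with thin microtomed sections in
  which scatter is mild.
* AsLS estimates the *lower envelope*. Where overlapping bands form a broad
  massif (the 1700/1728 cm^-1 carbonyl region), a few percent of the peak
  absorbance is absorbed into the baseline even on baseline-free input. A
  "corrected equals original" identity only holds approximately (max
  deviation below ~10% of peak absorbance, median near zero); the tests
  encode those measured bounds.

## MCR-ALS implementation

Each iteration performs two exact constrained half-updates:

* **C update**: for every pixel row, a Lawson–Hanson non-negative least
  squares (NNLS) solve against the current `S_t`, restricted to the
  components present in the pixel's image when a correspondence matrix is
  given. Restricting the support *inside* the solve (rather than zeroing
  afterwards) keeps each half-update an exact minimizer.
* **S update**: per-channel NNLS against the current `C`.

Because both half-updates are exact minimizers of the same objective, the
LOF trace is non-increasing — a property the test suite asserts on random
instances at 1e-8 relative tolerance, with the NNLS sub-solver checked
against brute-force support enumeration. The Gram matrices and projections
are computed in R via BLAS (`crossprod`); the C++ kernel only runs the tiny
k-variable active-set solves, so a 8192 x 276, k = 5 multiset iterates in
~30 ms.

`S_t` rows are rescaled to unit Euclidean norm after every iteration with a
compensating rescale of the `C` columns, so the product — and hence the LOF
trace — is unchanged. The scheduling of normalization is a free choice (it
does not alter the fit); per-iteration normalization keeps intermediate
magnitudes stable. The LOF itself is evaluated through the trace identity
`||D - CS||^2 = ||D||^2 - 2 tr(S'C'D) + tr(C'C SS')`, with a direct
recomputation when the identity indicates a near-exact fit, where the
identity would cancel catastrophically.

Convergence: stop when the relative LOF change falls below `tol` (default
0.1%) or after `max_iter` (default 50) iterations — conventional MCR-ALS
settings, both exposed. Noiseless recovery benchmarks use a tighter
`tol = 1e-4`% and a few hundred iterations: ALS approaches an exact
factorization along flat valleys, and the default tolerance would stop at
~0.2% LOF.

### SIMPLISMA initial estimates

Purity of pixel `i` is `sd_i / (mean_i + alpha)` over its spectrum, with
`alpha` defaulting to 1% of the largest pixel mean. After each pick,
candidates are down-weighted by the determinant of the
correlation-around-origin dispersion matrix of the already selected pixels
plus the candidate (length-scaled rows), which suppresses pixels collinear
with earlier picks. Selection is over *pixels*, so the initial estimates are
spectra. The exact variant in the original literature differs in small
details between publications; this one is tested against an exhaustive
re-computation of the same definition and against planted-pure-pixel
recovery.

### Rank selection

`select_rank` offers the scree-gap rule (the index maximizing `s_k/s_(k+1)`
over the first half of the scree — the restriction avoids spurious ratios in
the noise tail), a noise-floor count against `noise_sd * (sqrt(m) +
sqrt(n))`, and manual passthrough. On the default synthetic scene the gap at
the designed rank (5) dominates the largest structural ratio (~2.7 vs ~2.2)
across seeds; a much stronger baseline residual would blur it, which is the
realistic failure mode of scree-based rank selection.

### Presence estimation

After the preliminary unconstrained fit, component k is declared present in
image i when its mean concentration over the image's block reaches
`rel_threshold` times the largest such mean across images. For a
concentration matrix near the truth, leakage into absent blocks is
essentially noise and the spec-level default threshold (0.01) separates
cleanly — that contract is tested directly. For concentrations taken from an
*unconstrained ALS fit* of similar sapwood/heartwood lignins, rotational
leakage into absent blocks reaches 5–10% of the maximum, so the pipeline
wrapper `resolve_images()` uses 0.25 by default: comfortably above observed
leakage and far below the ~80–100% relative means of truly present
components. Both thresholds are arguments.

## The synthetic stated world

Real SR-FTIR sections of this kind are not publicly deposited, so the
generator stands in for them with known ground truth. It emulates:

* **Geometry** (32 x 32 px per ring, 8 rings): a periodic cell-wall lattice
  (period 10 px, thickness 2 px) with cell-corner pixels, lumen holes, and a
  vertical ray stripe (5 px). Tissue classes carry the constituents:
  cellulose on walls (weaker at corners, where the middle lamella dominates),
  lignins at cell corners > walls > ray, extractives confined to the ray,
  and a substrate blank alone in the lumina. Weights were chosen so that for
  every ordered pair of components some pixel class contains one at exactly
  zero and the other positive — the condition under which non-negativity
  pins the rotational ambiguity of the bilinear model and makes "recovery of
  the truth" a well-posed expectation. A smooth multiplicative texture
  (+-30%) varies the maps between rings.
* **Spectra**: sums of Gaussian bands (Lorentzian available) from the
  classical wood-FTIR assignments, unit 2-norm rows. The sapwood lignin
  carries the 1660 cm^-1 coniferyl alcohol/aldehyde band; the heartwood
  lignin replaces it with the 1640 cm^-1 carbonyl band; extractives carry
  taxifolin-like 1640 plus resin-acid 1700/1728 bands. Carbonyl-region
  widths are 18–22 cm^-1 so the band cluster remains resolvable after AsLS
  (wider bands merge into a massif that AsLS partially removes — with 26–30
  cm^-1 widths the extractives spectrum already loses ~2% of its energy to
  the baseline on clean input).
* **Ring series**: sapwood lignin present in rings 1..r, heartwood lignin
  from ring r on (default r = 5 of 8, both present at the transition ring) —
  the presence pattern that makes the transition zone identifiable.
* **Baseline**: one raised cosine per pixel, random phase, amplitude
  jittered +-25% around 0.02 a.u., period 1000 cm^-1 — a broad Mie-like
  oscillation roughly twice the window width.
* **Noise**: additive i.i.d. Gaussian, sd 0.006 a.u. = 1% of the default
  scene's maximum absorbance (~0.6 a.u.).
* **Saturation**: an optional fraction of pixels set to NaN and masked,
  mimicking detector saturation; masked pixels never enter the multiset.

What a green test establishes — and what it does not: the synthetic world
has exactly bilinear pixels, homoscedastic noise, a single smooth baseline
shape and component-pure tissue classes. Real tissue has correlated noise,
resonant-Mie distortions that *shift* bands (not just offset them),
constituent gradients within a wall, and no guarantee of pure pixels.
Passing recovery tests therefore validates the algorithmic chain, not the
identifiability of any particular real specimen.

## Band tracking and the transition ring

`roi_average` takes the unweighted mean spectrum over a mask (e.g. the ray),
`band_intensity` reads the windowed maximum in `center ± 10 cm^-1`
(optionally after subtracting the chord between window endpoints — a
windowed maximum rather than a fitted peak area, because visual reading of
band heights is what it replaces), and `transition_index` reports the first
ring where `I1640 / (I1640 + I1660) > 0.5`. The normalized ratio is
invariant to common rescaling of both series; on default scenes the
pre-transition ratio stays below ~0.45 and jumps above ~0.52 at the ring
where the heartwood lignin appears, so the 0.5 threshold has symmetric
margin. The 1640/1660 windows overlap (band centers 20 cm^-1 apart,
half-width 10), so each series carries a floor from the other band and from
the extractives' own carbonyl bands; the detection rule is a dominance
criterion, not a pure band height.

## Numerical choices and edge cases

* NNLS is solved on the normal equations (k <= ~10 unknowns), with partial
  pivoting and a tiny-pivot guard for rank-deficient supports.
* A component whose spectrum collapses to zero during ALS triggers a
  warning; its norm is left at 1 to avoid NaN propagation.
* `lack_of_fit` errors on an all-zero `D` (undefined denominator); `D = C =
  truth` yields exactly 0.
* Text serialization writes doubles at 17 significant digits, so every
  write-read cycle (ENVI, TSV container, long CSV) is bit-exact; the TSV
  directory container replaces HDF5, which has no reader in this R
  toolchain.
* Axes are normalized to ascending order on construction; a descending
  stored axis is reversed and flagged in the metadata.
* All generator randomness derives from one integer seed via fixed
  per-(image, component) substreams, so maps are reproducible individually
  and the global RNG stream of the session is never disturbed.

## Known limitations

* No resonant-Mie EMSC correction; AsLS removes smooth additive baselines
  only, and only their slow part (see above).
* Rank selection by scree gap is fragile when baseline residuals rival the
  weakest component; the noise-floor and manual methods are the fallbacks.
* No rotational-ambiguity band boundaries, trilinearity, or local-rank
  analysis; uniqueness on real data is not guaranteed and is not claimed.
* The ROI masks for band tracking are user-supplied; nothing registers
  sections spatially.
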