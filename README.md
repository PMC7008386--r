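# hsimcr — multiset MCR-ALS unmixing of FTIR hyperspectral images

`hsimcr` resolves series of mid-infrared absorbance images of plant tissue
into constituent pure spectra and per-image distribution maps. It was built
for the analysis situation of synchrotron-FTIR imaging of softwood sections
cut across consecutive annual rings, where one wants to follow how the
chemistry of cell walls, rays and extractive deposits changes from sapwood
to heartwood — but every pixel is a mixture, the spectra ride on broad
Mie-scatter baselines, and parts of each image are oversaturated.

For whom: spectroscopists and plant cell-wall researchers analyzing
hyperspectral FTIR (or Raman) image series in R, and methods developers who
need a tested, ground-truthed harness for multiset curve resolution.

## The model

Unfolded to a pixels x wavenumbers matrix, an absorbance image follows the
Beer–Lambert bilinear model

```
D = C S' + E,    C >= 0 (pixels x k),   S' >= 0 (k x channels)
```

Several images sharing one spectral axis are stacked row-wise into a
*multiset* and factored jointly: one spectra matrix `S'` for all images, one
concentration block per image, refolded into that image's k distribution
maps. The factorization is computed by alternating exact non-negative least
squares (MCR-ALS) under spectra normalization (unit 2-norm rows of `S'`,
with compensating rescale of `C`) and an optional *correspondence of
species* constraint: components declared absent in an image have their
concentration block held at exactly zero. Fit quality is the lack of fit,
`LOF = 100 * sqrt(sum(E^2)/sum(D^2))`.

The supporting cast: window truncation to 1200–1750 cm⁻¹, asymmetric least
squares (AsLS) baseline/scatter correction, SIMPLISMA purest-pixel initial
estimates, SVD scree rank selection, automated per-image presence
estimation, Savitzky–Golay smoothing for point spectra, band-intensity
tracking across rings, and localization of the sapwood→heartwood transition
ring from the 1640/1660 cm⁻¹ band pair.

Because the kind of data this targets is rarely deposited, the package
includes a first-class synthetic generator (`scene_params()`,
`simulate_multiset()`) that emulates ring series of wood cross sections —
cell-wall lattice, cell corners, ray, lumina; five constituents with
literature band positions; Mie-like baselines; noise; saturated-pixel masks
— and returns the ground truth (`C`, `S'`, baselines, presence) for recovery
testing.

## Worked example

```r
library(hsimcr)

scene <- scene_params(seed = 1)          # 8 rings, 32x32 px, 5 constituents
sim <- simulate_multiset(scene)
sim$images[[1]]
#> <spectral_image 32x32 px, 276 channels [1200..1750 cm-1], 1024 valid px>

res <- resolve_images(sim$images, tol = 0.001, max_iter = 300)
res$k                                    # rank selected from the SVD scree
#> [1] 5
res$model
#> <mcr_model: k=5, 8192 rows, 62 iter, LOF 8.931%, converged>
res$presence * 1L                        # estimated presence per ring
#>     [,1] [,2] [,3] [,4] [,5]
#> DX1    0    1    1    1    1
#> DX2    0    1    1    1    1
#> DX3    0    1    1    1    1
#> DX4    0    1    1    1    1
#> DX5    1    1    1    1    1
#> DX6    1    1    1    1    0
#> DX7    1    1    1    1    0
#> DX8    1    1    1    1    0

# spectral recovery vs. the generator's ground truth
round(match_components(res$model, sim$truth)$correlations, 3)
#> [1] 0.999 0.996 0.992 0.998 1.000

# where does heartwood formation start? track the 1640/1660 band pair in the ray
ray <- tissue_masks(scene$image_shape, scene$tissue_geometry)$ray
transition_index(track_band(sim$images, ray, 1640),
                 track_band(sim$images, ray, 1660))
#> [1] 5
```

Reading the output: the scree gap picks five components; the constrained fit
converges at 8.9% LOF (the injected noise floor); the estimated presence
matrix says component 5 (matched to sapwood-type lignin, its 1660 cm⁻¹ band)
disappears after ring 5 while component 1 (heartwood-type lignin, 1640 cm⁻¹)
appears from ring 5 — so ring 5 is the transition zone, which the
ratio-based `transition_index` confirms. All five resolved spectra correlate
≥ 0.99 with the generating truth.

Maps refold with `refold(res$multiset, res$model$C[, j], "DX5")` or all at
once with `refold_all`; `export_report()` writes spectra, maps, LOF trace,
presence and run metadata as plain-text tables.

## Command line

A thin CLI ships in `inst/cli/hsimcr` (simulate / preprocess / fit /
report); cubes and multisets are exchanged as plain-text container
directories, ENVI header+binary, or long CSV (`?save_image`).
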