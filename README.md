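# stimri — tissue-mode intensity standardization for brain MRI

Conventional T1-weighted MR intensities have no absolute meaning: the same
tissue shows different values across scanners, sites and sessions, which
breaks intensity-based analyses in multicenter studies. `stimri` maps
images onto the intensity scale of a fixed *standard image*. It is aimed
at neuroimaging pipelines in which images are already denoised,
bias-corrected, spatially registered to the standard grid and clamped to a
common 0–100 scale — the package supplies the standardization step, the
classic comparator, the evaluation protocol, and a synthetic phantom
study to validate all of it.

## The method

**STI** exploits the spatial correspondence that registration established.
For each tissue X ∈ {BKG, WM, GM} (searched in that order, largest
component first) it:

1. keeps the voxels of tissue X's mask;
2. computes the standard-versus-input joint intensity histogram of those
   voxels — bin width 0.25 units, 400 × 400 bins over [0, 100] — and
   smooths it with an isotropic Gaussian of FWHM 10 bins;
3. takes the histogram mode: its coordinates (m<sub>r,X</sub>,
   m<sub>s,X</sub>) are the most frequent input↔standard intensity
   correspondence for tissue X.

Each search shields the next: voxels with input intensity up to 10 units
above the BKG mode are dropped before the WM search, and voxels within
25 units below (or anywhere above) the WM mode are dropped before the GM
search. The transfer function is the piecewise-linear interpolation of

&nbsp;&nbsp;S<sub>STI</sub> = {(0,0), (m<sub>r,BKG</sub>, m<sub>s,BKG</sub>),
(m<sub>r,GM</sub>, m<sub>s,GM</sub>), (m<sub>r,WM</sub>, m<sub>s,WM</sub>),
(100,100)},

applied voxel-wise. **L4**, the comparator, matches the nine foreground
deciles (foreground = voxels ≥ whole-image mean and < the whole-image
99.8th percentile), the whole-image 99.8-percentile pair and the two
boundary pairs — twelve landmarks, no spatial information. Evaluation uses
the voxelwise mean absolute error MAE = (1/N) Σ<sub>v</sub>
|I<sub>o,v</sub> − I<sub>s,v</sub>| over the standard image's foreground,
WM and GM voxel sets (in percent, since the scale is 0–100), with paired
t-tests between techniques.

## A worked example

```r
library(stimri)

ph    <- generate_phantom(phantom_spec(seed = 42))        # standard + masks
site  <- distortion_spec(function(v) 100 * (v / 100)^1.25,  # a "scanner"
                         noise_sd = 2, seed = 7)
input <- distort_volume(ph$volume, site)

res <- standardize_sti(input, ph$volume, ph$masks)
res$report$landmarks
#> <landmark_set> 5 pairs
#>  label   input standard
#>    min   0.000    0.000
#>    BKG   0.625    2.375
#>     GM  36.625   44.875
#>     WM  69.875   75.125
#>    max 100.000  100.000

wm <- voxel_set(ph$masks$wm, "WM")
mean_absolute_error(input, ph$volume, wm)        # before: 5.222247
mean_absolute_error(res$volume, ph$volume, wm)   # after:  1.36941
```

The gamma-style site transfer darkens WM from 75 to ≈69.8 and GM from 45
to ≈36.9; the estimated landmarks sit within a fraction of a unit of
those ground-truth correspondences (the standard-axis coordinates are
within one 0.25-unit bin of the true tissue means), and applying the
mapping cuts the WM error from 5.2% to 1.4% — close to the ≈1.6%
irreducible floor set by the site noise alone.

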