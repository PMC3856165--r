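# motilindex

Quantifies structural motility of cells with dense, fine processes —
astrocytes, radial glia and other heavily ramified cell types whose
hundreds of overlapping filopodia defy per-process tracking — from
single-channel fluorescence time-lapse series.

## The method

Frames (or maximum-intensity projections of z-stacks) are binarized by
Sobel edge detection and dilated with a 6 px disk, giving masks
I<sub>xy</sub>(t) ∈ {0,1}. Consecutive masks are subtracted and the
absolute difference δ<sub>xy</sub>(t) = |I<sub>xy</sub>(t+1) −
I<sub>xy</sub>(t)| marks redistributed (added or lost) pixels. Two
per-interval indices are computed:

* **M1 (area-normalized):** M1(t) = R(t)/Ā, with R(t) = Σδ the
  redistributed-pixel count and Ā the mean mask area over all time
  points. Simple, but coupled to the projected cell area.
* **M2 (boxcar-weighted):** δ is smoothed with a w×w moving average
  (default w = 9), multiplied back onto δ, and averaged over the N
  changed pixels: M2(t) = (1/N) Σ δ̂·δ ∈ [0, 1]. Clustered changes
  (real remodeling) are up-weighted, isolated flicker (artifact) is
  suppressed, and the value is independent of total cell size.

For rapid acquisitions (≈ 20 s frame interval) a per-pixel temporal
filter removes artifact before indexing: each pixel's binary trace is
Fourier-transformed and pixels whose dominant frequency exceeds
0.0026 Hz (periods < ~6.4 min) are held at their temporal majority
value.

A synthetic movie generator (`generate_movie()`, `generate_pair()`)
renders soma-plus-filopodia cells with reflected-random-walk tip
kinetics, known ground truth and configurable imaging artifacts, so the
whole pipeline is verifiable without microscopy data.

## Worked example

```r
library(motilindex)

mv    <- generate_movie(synthetic_preset("motile", seed = 7, n_frames = 30))
masks <- preprocess_series(mv$series)          # Sobel + 6 px dilation
res   <- motility_index(masks, w = 9)
res
#> <motility_result> 29 intervals, dt = 20 s
#>   mean M1 = 0.0964814  (mean area 3823.5 px)
#>   mean M2 = 0.233768  (boxcar w = 9)

tidy(res)   # per-interval table (t, R, areas, M1, M2, N)
#> # A tibble: 29 × 8
#>       t time_s     R   A_t  A_t1     M1    M2     N
#>   <int>  <dbl> <int> <int> <int>  <dbl> <dbl> <int>
#> 1     1     10   469  3817  3866 0.123  0.308   469
#> 2     2     30   286  3866  3714 0.0748 0.199   286
#> ...

fm <- classify_pixels(masks, threshold = 0.0026)
fm
#> <frequency_mask> 96 x 96 px, threshold 0.0026 Hz (Nyquist 0.025 Hz)
#>   rejected 731 / 9216 pixels
motility_index(apply_filter(masks, fm))$m2_mean
#> [1] 0.2128
```

The motile cell scores mean M2 ≈ 0.23 (its ground-truth mean tip speed
is 1.87 px/frame), and temporal filtering trims only the artifact
share (→ 0.21). The same analysis on the artifact-only `"fixed"`
preset gives M2 0.098 → 0.052, a 47 % reduction — the filter removes
far more of a dead cell's apparent "motility" than a live one's,
because a fixed cell's index is mostly noise.

`autoplot()` methods plot results directly; `boxcar_sweep()` explores
the window width; `run_pipeline()` batch-processes TIFF movies to CSV
with a JSON run record; `inst/scripts/motilindex.R` wraps the same
functions as a command line with `compute`, `tfilter`, `simulate`,
`sweep` and `compare` subcommands.

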