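# neuropil

Decontamination of calcium-imaging fluorescence traces by local neuropil
separation.

## The problem

In two-photon calcium imaging the point spread function is elongated
axially, so the trace measured inside a somatic region of interest (ROI)
is a mixture: the soma's signal plus out-of-focus fluorescence from the
surrounding neuropil and, sometimes, an overlapping cell. When neuropil
activity is itself modulated by the experiment (stimuli, locomotion), the
contamination biases every downstream statistic. This package removes it,
given pre-defined ROIs (hand-drawn or from any segmentation tool — it
contains no cell detection).

## The method

For each ROI with mask trace `f_roi`:

1. **Grow** the surrounding neuropil by alternating cardinal/diagonal
   binary dilation until the ring (expansion minus ROI) reaches `N` times
   the ROI area, and **split** it into `N = 4` equal angular wedges about
   the ROI centroid — giving `N + 1` measurement regions.
2. **Demix** the `(N+1) x T` matrix `F` of region-mean traces by sparse
   non-negative matrix factorization, `F ≈ V S` with `V, S ≥ 0`,
   minimising

   `E = ½‖F − VS‖² + α l₁(‖V‖₁ + ‖S‖₁) + α(1 − l₁)(‖V‖² + ‖S‖²)`

   (defaults `α = 0.1`, `l₁ = 0.5`, `N + 1` components, nndsvd
   initialisation, HALS updates).
3. **Select** the somatic component: normalise each column of `V` to sum
   one and take the column `j` with the largest relative presence in the
   ROI row; the decontaminated trace is `f_est = V[1, j] · S[j, ]`. The
   somatic signal is the one concentrated in the ROI; neuropil is present
   everywhere.

Classical subtraction (`f_roi − k f_npil`) is included as the comparison
baseline, along with Δf/f₀ utilities (f₀ = 5th percentile of the 1 Hz
low-passed trace), zero-phase low-pass filtering, and the locomotion
modulation index `(R_L − R_s)/(R_L + R_s)`.

A full synthetic-movie generator with ground truth (Poisson spiking,
GCaMP6-style indicator kinetics with a saturating cubic nonlinearity,
doughnut-shaped cell kernels, a Wiener-process background with a
stimulus square wave, Poisson shot noise) makes the whole pipeline
testable end to end. See `vignettes/neuropil-methods.Rmd` for the model,
parameter meanings and numerical choices.

## Worked example

Simulate the hardest benchmark scene (a central cell plus an overlapping
cell and a bright localized source), then decontaminate the central cell:

```r
library(neuropil)
sim <- render(benchmark_scene("C", seed = 99, duration = 60))
sim
#> <sim_output: 3 cell(s), 80 x 80 px, 6000 frames @ 100 Hz>
res <- run_pipeline(sim$movie, sim$masks[1], output_dir = "demo")
res$cell01$separation
#> <separation_result (nmf): 5 regions, 5 components, selected #3>

src <- lowpass(sim$source_traces[[1]], 5, 100)
cat(sprintf("measured %.3f, subtraction %.3f, separated %.3f\n",
  pearson(lowpass(res$cell01$traces$values[1, ], 5, 100), src),
  pearson(lowpass(res$cell01$subtraction, 5, 100), src),
  pearson(lowpass(res$cell01$somatic, 5, 100), src)))
#> measured 0.719, subtraction 0.865, separated 0.999
```

The numbers are Pearson correlations between each extracted trace and the
central cell's noise-free source signal (both 5 Hz low-passed): the raw
ROI mean is heavily contaminated (0.72), ring subtraction helps but is
damaged by the bright contaminant's negative transients (0.87), and the
NMF separation recovers the source almost exactly (1.00). `demo/`
contains one CSV per ROI (measured, somatic, subtraction, Δf/f traces)
and a `parameters.log`.

For real data, replace the simulated inputs with a TIFF path and an
ImageJ ROI archive:

```r
run_pipeline("movie.tif", "RoiSet.zip", "results", frame_rate = 30)
```

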