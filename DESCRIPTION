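Package: neuropil
Title: Neuropil Decontamination of Calcium Imaging Signals by Blind Source Separation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes out-of-focus neuropil contamination from fluorescence
    traces of pre-defined regions of interest (ROIs) in calcium imaging
    movies. For each ROI the surrounding neuropil is grown by alternating
    cardinal and diagonal morphological dilation until it reaches a set
    multiple of the ROI area, split into equal angular subregions, and the
    region-mean traces are demixed by sparse non-negative matrix
    factorization (optionally independent component analysis); the separated
    component most strongly present in the ROI is returned as the somatic
    signal. Includes ImageJ ROI file import/export, multi-page TIFF movie
    handling with a streaming mode, baseline (5th percentile of the 1 Hz
    low-passed trace) and delta-f/f utilities, a classical neuropil
    subtraction method for comparison, and a full synthetic-movie generator
    (Poisson spiking, GCaMP6 indicator dynamics with a saturating cubic
    nonlinearity, doughnut-shaped cell kernels, Wiener-process background and
    Poisson shot noise) with ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
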