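Package: topostat
Title: Topological Statistical Mapping for Sensor-Level M/EEG Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts epoched multichannel EEG/MEG recordings into NIfTI
    summary-statistic images (interpolated scalp maps stacked over
    peristimulus time, and time-frequency planes), smooths them with
    Gaussian kernels specified in physical units, fits mass-univariate
    general linear models voxel by voxel, and corrects the resulting t and
    F maps for multiple comparisons with random field theory at peak and
    cluster level, including window-restricted (small-volume) searches.
    Also provides Morlet wavelet time-frequency decomposition,
    Gaussian-weighted time-window and wavelet energy summaries of trial
    ensembles (evoked, induced, and per-trial modes), rigid
    sensor-to-head coregistration by landmark Procrustes fitting and
    iterative closest point alignment, icosphere surface generation, and
    a synthetic-data module that generates epoched datasets and smooth
    Gaussian null fields with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    interp,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
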