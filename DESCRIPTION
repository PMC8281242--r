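Package: tmteeg
Title: Tablet Trail Making Test Kinematics and EEG Task Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of tablet-administered Trail Making Test
    (TMT) sessions with simultaneous electroencephalography (EEG). Generates
    synthetic block-design sessions (stimulus layouts, stylus traces, EEG with
    condition-dependent oscillatory amplitude and task triggers); segments
    stylus speed time-courses into linking and non-linking periods by an
    adaptive speed threshold and scores links, errors and seconds-per-link;
    runs the non-parametric behavioural statistics (Kolmogorov-Smirnov,
    Wilcoxon signed rank, Kruskal-Wallis with Dunn-Sidak post hoc screening,
    bootstrap bin confidence intervals); preprocesses EEG (EDF/BrainVision
    input, downsampling, zero-phase FIR band-pass, ICA-based artifact removal,
    mean-mastoid re-reference, baseline-anchored epoching); extracts
    dB-normalized band power via a 20-frequency complex Morlet wavelet bank;
    and fits task partial least squares with permutation inference, bootstrap
    ratios, contrast saliences and FDR-thresholded electrode maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    e1071,
    ica,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
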