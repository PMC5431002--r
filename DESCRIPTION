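Package: ictal
Title: Seizure-Risk Statistics and Seizure-Similarity Classification for
    In Vivo Ictogenesis Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying seizure risk and seizure similarity in
    injection-based ictogenesis experiments on epileptic animals. Implements
    Poisson seizure-rate estimation and one-degree-of-freedom chi-square rate
    tests, a kernel-smoothed Nelson-Aalen estimate of the time-dependent
    seizure hazard with an Epanechnikov kernel and a 5-minute at-risk rule,
    a 44-feature battery for single-channel hippocampal EEG seizures (band
    powers, alpha-delta ratio, peak frequency, line length, spike-train
    statistics, Teager-Kaiser energy, seizure length), Morlet wavelet
    spectrograms, and a per-animal normalization / PCA / one-class SVM
    pipeline that classifies whether any seizure is similar to a given
    animal's spontaneous seizures. A synthetic-data module simulates seizure
    event timelines (inhomogeneous Poisson with refractory gaps) and
    stereotyped per-animal seizure EEG so the whole pipeline can be exercised
    end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
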