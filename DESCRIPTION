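Package: sleepLFP
Title: Sleep Oscillation Detection and Hippocampal-Cortical Coupling in
    LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and characterization of the NonREM sleep
    oscillations that support memory consolidation in rodent
    local field potential (LFP) recordings: hippocampal sharp-wave
    ripples, cortical sleep spindles and delta waves.  Provides
    zero-phase preprocessing (anti-aliased decimation, band-pass
    filtering, artifact blanking), sleep-architecture statistics,
    an automatic NonREM-like/REM-like state classifier for
    anesthetized recordings (PCA + 2-means on multitaper spectral
    features), delta-spindle-ripple temporal sequence and
    co-occurrence analysis, slow-oscillation phase locking with
    circular statistics, aperiodic (1/f) spectral parameterization
    of power spectra as an excitation/inhibition proxy, and an
    object-exploration discrimination index.  A ground-truthed
    synthetic LFP generator makes every stage testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
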