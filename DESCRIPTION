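Package: barosens
Title: Spontaneous Cardiac Baroreflex Sensitivity and Heart-Rate
    Variability from Beat-to-Beat Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies spontaneous cardiac baroreflex sensitivity (cBRS)
    and heart-rate variability (HRV) from beat-to-beat arterial pressure
    and electrocardiogram recordings. Implements R-peak detection, per-cycle
    systolic/diastolic/mean pressure extraction, breath detection from
    respiratory flow, artifact (ectopy) flagging, cubic-spline resampling of
    RR and systolic-pressure tachograms to an equidistant 4 Hz grid, Welch
    auto- and cross-spectral estimation with linear detrending and a Hanning
    window, transfer-function gain/phase/coherence with VLF/LF/HF band
    summaries (the low-frequency gain being the cBRS index), time- and
    frequency-domain HRV metrics (RMSSD, pNN50, band powers, normalized
    units), and a closed-loop cardiovascular variability simulator with a
    known baroreflex gain for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
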