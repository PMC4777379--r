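Package: emophys
Title: Psychophysiological Affect Recognition from Multimodal Biosignals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for affect recognition from
    peripheral physiology recorded under a picture-block emotion-induction
    paradigm. Generates synthetic multichannel recordings (facial EMG over
    corrugator supercilii and zygomaticus major, skin conductance level,
    blood volume pulse) with controllable age, gender and condition effects;
    preprocesses the channels (zero-phase Butterworth band-pass, power-line
    notch, RMS envelope, low-pass smoothing, beat detection with automatic
    artifact screening); extracts twenty heart-rate-variability, facial-EMG
    and electrodermal features per subject and affective condition; removes
    redundant features by pairwise-correlation thresholding; screens age,
    gender-role and personality scores against every feature with Bonferroni
    control; and classifies core affects with a support vector machine under
    leave-one-subject-out validation, with wrapper feature selection and
    gender- and age-specific subgroup analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
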