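Package: dreamsift
Title: Dream Versus Dreamless Sleep Classification From EEG With
    Minimal Channel Subsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to classify sleep-EEG segments into dream and
    dreamless states and to search for minimal informative channel
    subsets. Implements a preprocessing chain for multichannel EEG
    (mastoid re-referencing, resampling, zero-phase band-pass
    filtering, fixed-length segmentation), two feature paths (common
    spatial patterns with PCA and standardization; a discrete wavelet
    transform battery of fractal-dimension, energy, Hjorth and moment
    features per sub-band), a stable of standard classifiers with
    stratified and leave-one-subject-out cross-validation,
    permutation-based channel importance, and a six-objective NSGA-II
    channel-subset search with Pareto-front extraction. A synthetic
    EEG generator with planted class effects, plus EDF import/export,
    makes every stage testable without access to polysomnography
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    class,
    glmnet,
    nnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    withr
Config/testthat/edition: 3
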