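Package: eegaze
Title: Decoding Eye Fixations and Gaze Location from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid convolutional / recurrent / Transformer architectures for
    decoding eye-related information from multichannel EEG epochs. Implements
    two end-to-end decoder families - a 2-D convolutional front end followed by
    an LSTM summary (Model A, with temporal- and spatial-Transformer variants)
    and a per-channel 1-D convolutional front end followed by per-segment
    spatial Transformer encoders with a CLS summary token and an LSTM (Model B)
    - for binary fixation classification and 2-D gaze-coordinate regression.
    Includes signal-cropping and channel-reduction protocols, the 1/(2n)
    RMSE/MAE conventions, multi-seed experiment aggregation, an
    attention-derived per-channel importance statistic with topographic export,
    and a fully seeded synthetic EEG generator with planted gaze-informative
    channels for ground-truth evaluation. All networks and their
    backpropagation are implemented in base R matrix code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
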