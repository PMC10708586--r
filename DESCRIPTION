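Package: eegrecon
Title: Digit Decoding and Visual-Saliency Reconstruction from 14-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes visually evoked 14-channel EEG into ten digit categories with a
    depthwise one-dimensional convolutional network, maps the classifier's internal
    feature vector to a visual-saliency image through an adversarially trained
    generator, and transfers the trained generator weights to reconstruct the
    original digit stimulus. Includes a reader/writer for the MindBigData
    tab-separated line dialect, a class-conditioned synthetic EEG and stimulus
    generator so the whole pipeline runs without external recordings, saliency and
    classification evaluation metrics (SIM, SSIM, CC, Cohen's kappa), a per-class
    GAN for EEG data augmentation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
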