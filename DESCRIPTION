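Package: stressfuse
Title: Multimodal EEG-ECG Stress Detection with Attention-Based Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for three-class psychological stress detection
    (baseline, stress, amusement) from paired electroencephalogram (EEG) and
    electrocardiogram (ECG) recordings. Transforms 14-channel EEG into
    128x128x3 Morlet-wavelet band scalograms (theta, alpha, beta) via
    zero-phase Butterworth filtering, common average referencing, epoching and
    ICA artifact removal; transforms single-lead ECG into cleaned raw segments
    and a 25-feature heart-rate-variability panel via Pan-Tompkins QRS
    detection. A dual-pathway network with three convolutional backbone
    adapters (VGG16, EfficientNetB0, ResNeXt50-32x4d), token self-attention
    per modality and a learned cross-modal softmax gate fuses the two
    modalities; training follows a cosine-annealed, label-smoothed,
    subject-independent protocol. A seeded synthetic-signal generator with
    condition-dependent band power and RR dynamics makes every stage testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
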