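Package: flypose3d
Title: Multi-Camera 3D Pose Estimation and Behavioral Embedding for Tethered Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for markerless 3D limb and appendage tracking of small
    tethered animals filmed by a ring of synchronized cameras. Implements a
    pinhole-plus-radial-distortion projection model, SVD triangulation,
    pattern-free self-calibration of camera extrinsics and distortion by
    Huber-robust bundle adjustment using the animal's own keypoints,
    extraction of multiple keypoint hypotheses from detector probability
    maps, correction of 2D detection errors with a tree-structured pictorial
    structures model solved by max-sum belief propagation, reprojection-based
    quality control and active-learning frame selection, and an unsupervised
    behavioral embedding pipeline (joint angles, Morlet wavelet posture
    dynamics, t-SNE with Kullback-Leibler dissimilarities, and
    watershed-segmented behavioral maps). A synthetic-scene generator
    provides camera rigs, articulated gait motion and probability maps with
    controlled corruptions for validation at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan
Config/testthat/edition: 3
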