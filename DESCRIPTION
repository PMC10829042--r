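Package: dscapsp
Title: Dynamic Spatial-Channel Attention PSPNet for Crop-Field Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of sugarcane fields in high-resolution RGB
    satellite imagery with DSCA-PSPNet: a dilated ResNet34 backbone and pyramid
    scene parsing decoder augmented with dynamic squeeze-and-excitation (D-scSE)
    attention blocks whose spatial and channel branches are fused by learnable
    scalar weights. Includes a self-contained CPU neural-network engine
    (convolution, batch normalisation, pooling, bilinear upsampling, backprop,
    AdamW), a scene-tiling and augmentation pipeline with per-scene
    train/validation/test allocation, pixel-confusion evaluation metrics
    (IoU, accuracy, precision, recall, F1), a model profiler (parameters,
    FLOPs, parameter memory) with attention-map extraction, and a seeded
    synthetic satellite-scene generator so the whole pipeline runs at desk
    scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
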