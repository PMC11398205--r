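Package: finsim
Title: Virtual Fish Imagery for Training In-Tank Detection Models
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates computer-simulated underwater image datasets for
    recirculating-aquaculture (RAS) fish detection. A Boids particle model
    simulates fish schooling in a cylindrical tank with collision avoidance,
    a containment lid, paired vortex forces and a cuboid deflection barrier;
    a software rasterizer renders each school state through a wide-field
    pinhole camera into co-registered RGB, depth and instance-index layers;
    a distance-based turbidity model darkens and blurs with range; the
    instance layers are converted automatically into filtered COCO
    bounding-box annotations; dataset builders mix virtual and real image
    manifests at configurable ratios with real-only validation/test splits
    and photometric augmentation; and an evaluation module scores detections
    with IoU-matched average precision (mAP0.5) and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
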