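Package: occubal
Title: Occlusion-Aware Copy-Paste Balance Augmentation for Fruit Detection Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for balancing multi-type occlusion object-detection datasets
    by synthetic copy-paste augmentation. Annotation boxes carrying one of eight
    occlusion classes (none, leaf, fruit, branch and their combinations) are
    counted per orchard region and illumination, per-cell synthesis deficits
    toward a global balance target are planned, occluded apple crops are
    synthesized from no-occlusion crops and a pool of segmented occlusion
    elements under grid-constrained geometric rules, packed onto fruit-free base
    images with automatically generated labels, and merged into a balanced
    training set. Includes Pascal VOC XML and YOLO txt readers/writers, a
    luminance-based illumination partitioner, VOC-style precision/recall/AP/mAP
    evaluation, and procedural toy-data generators so the whole pipeline is
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    xml2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
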