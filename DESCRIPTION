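Package: cholescan
Title: Gallstone Detection on CT-Like Images with Anatomical-Context
    Confidence Rescoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable single-stage grid/anchor detector
    pipeline for identifying cholelithiasis and classifying gallstones
    (granular vs muddy) on abdominal CT-like images. Provides a synthetic
    abdominal phantom generator with ground truth over five object classes
    (spine, liver, gall, granular stone, muddy stone), a small fully
    convolutional detector with YOLO-style anchor-box encoding and decoding,
    a rule-based anatomical-context policy that rescales gallstone
    confidences by the co-occurrence of liver and gallbladder detections,
    slice curation, AP/mAP evaluation, and a k-fold cross-validation
    harness. Reads and writes PNG images, YOLO-txt and COCO-JSON
    annotations, and tab-separated evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
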