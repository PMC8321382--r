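Package: cytovote
Title: Majority-Vote Ensemble Classification of Pap-Smear Cell Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for cervical-cytology image
    classification from nucleus marks: nucleus-centered cropping of field
    images, Bethesda class grouping into 2-, 3- or 6-way targets,
    augmentation-based class balancing with exact count planning, stratified
    shuffle-split partitioning, small convolutional classifiers with a
    dropout+softmax head, one-vs-rest precision/recall/F1/accuracy/
    specificity reports, and a recall-ranked majority-vote ensemble. Ships a
    seeded synthetic field-image generator so the whole pipeline runs
    without any external image collection.
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
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
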