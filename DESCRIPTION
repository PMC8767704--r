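Package: leafhair
Title: Ordinal Scoring of Cotton Leaf Hairiness from Microscope Images
Version: 0.1.0
Authors@R:
    person("leafhair", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A four-part image-classification pipeline that scores cotton
    leaf hairiness (pubescence) on the breeder's 9-class ordinal 1-5+ scale
    from abaxial microscope images: a data-augmentation module
    (resize/normalise plus stochastic flips, crops, rotations and Gaussian
    noise), a residual-network feature extractor of configurable depth with
    its classification layer removed, a single fully connected scoring
    layer, and a leaf-level scoring module reporting image accuracy, first
    image accuracy and majority-vote leaf accuracy.  Also implements
    leaf-group-exclusive dataset splitting over leaf number, year and
    growth environment, repeated validation-train resampling, a two-step
    genotype de-identification protocol, and a procedural generator of
    labelled synthetic leaf images so the whole pipeline is testable
    without the original dataset or a GPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    jpeg,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
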