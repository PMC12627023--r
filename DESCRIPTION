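Package: cadffnet
Title: Dual-View Convolutional Regression of Leaf Moisture Content
Version: 0.1.0
Authors@R: person("cadffnet", "maintainers", email = "cadffnet@example.org",
    role = c("aut", "cre"))
Description: Estimates leaf moisture content (percent of fresh mass) from
    paired front/back RGB images with a dual-branch residual convolutional
    network. The two branches interact through a shared efficient channel
    attention module (adaptive 1-D kernel over the channel descriptor of the
    summed branch features) and are fused by a multi-scale convolutional
    module with softmax-weighted 3x3/5x5 branches and a residual connection.
    Includes a deterministic synthetic dual-view leaf renderer, manifest and
    image I/O, a k-fold cross-validation training harness with Adam, and an
    ablation grid runner. All network math is implemented natively (im2col +
    BLAS) so the package runs on a single CPU with no deep-learning
    framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
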