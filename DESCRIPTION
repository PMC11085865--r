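Package: tetdia
Title: Multi-State ECG Image Diagnosis of Coronary Artery Disease from
    Treadmill Exercise Test Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for diagnosing coronary artery disease (CAD)
    from treadmill exercise test (TET) report images.  A report consists of
    three 12-lead ECG pages recorded before, during, and after exercise
    (pretest, exercise, recovery).  The package preprocesses report pages
    (state identification from banner text, cropping, grayscale conversion,
    binarization), splits each page into 12 per-lead patches and assembles a
    36-channel multi-state tensor, and classifies it with TETDiaNet, a
    convolutional network whose basic unit couples a depthwise (intra-state)
    spatial convolution with a per-lead grouped 1x1 (inter-state) convolution.
    Includes a synthetic TET-report generator with a controllable
    state-dependent ST-segment class effect, diagnostic metrics (sensitivity,
    specificity, precision, NPV, ROC/AUC), subgroup analysis by gender and
    age, and an analytic multiply-accumulate (MAC) complexity counter with a
    reference ResNet18 count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
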