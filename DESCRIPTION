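Package: colonychannels
Title: Quantification of Intra-Colony Channel Morphology in Biofilm Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the width of nutrient-transporting intra-colony
    channels in fluorescence images of bacterial colony biofilms. A colony
    is segmented by mean-gray-level thresholding, unwrapped about its
    centroid into polar (radius x angle) coordinates, contrast-enhanced
    (CLAHE), despeckled and inverted so channels appear as intensity peaks
    on circumferential profiles. Channel widths are taken as the
    full-width at half-maximum of prominence-filtered peaks and converted
    to micrometres by arc-length geometry. Widths are sampled on a radial
    grid, robustly filtered with a modified z-score (median absolute
    deviation) rule, characterised by linear and exponential radial
    trends, and compared across growth conditions with Mann-Whitney U
    tests. A synthetic colony generator with programmable channel width
    laws provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    EBImage,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
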