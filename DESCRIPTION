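Package: soursentinel
Title: Effluent Community Indicators of Sulfide-Producing Biofilm Mitigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects successful mitigation of sulfide-producing (souring)
    biofilms from planktonic (effluent) 16S amplicon time series collected
    from up-flow bioreactor columns. Implements phase segmentation of
    sulfide concentration series under nitrate treatment, 16S copy-number
    correction and genome-level aggregation of amplicon count tables,
    selection of specific sulfate-reducing bacterial populations (SSPs),
    relative-abundance anomaly statistics and critical-time-point
    detection, absolute SSP cell abundances via flow-cytometry scaling
    with Tukey-fence outlier removal, predicted dissimilatory sulfate
    reduction pathway trend analysis, alpha/beta diversity summaries, and
    a synthetic bioreactor experiment generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mgcv,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
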