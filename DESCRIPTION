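Package: stackstab
Title: Fiduciary-Free Stabilization of Time-Lapse Microscopy Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects lateral stage jitter and drift in multi-sample
    time-lapse microscopy without fiduciary markers. Frame-to-frame
    displacement is estimated by sub-pixel phase cross-correlation or by
    the median of a dense Lucas-Kanade optical-flow field, accumulated
    into a per-frame correction trajectory, and applied as a single
    bilinear translation per frame with selectable reframing (maximum,
    minimum, center, or reference framing). Includes a parametric
    stage-jitter synthesizer and a synthetic microscopy scene generator
    for ground-truth benchmarking, plus evaluation tools for displacement
    dispersion, all-pairs coherence analysis, and free-parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
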