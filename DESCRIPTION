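Package: caevents
Title: Multiscale Detection and Distilling of Cytosolic Calcium Events in Islet Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of confocal calcium-imaging movies of pancreatic
    islet cell collectives recorded in photon-counting mode. Provides rigid motion
    correction on temporally rebinned movies, semi-automatic cell segmentation by
    two-scale (difference-of-Gaussians) bandpass filtering and local-peak pixel
    climbing, Poisson-aware z-score normalization of summed region-of-interest
    traces with an iteratively estimated slow component, candidate event detection
    across a geometric ladder of timescales, and distilling of cognate candidates
    into real events characterized by start time, height and halfwidth. Downstream
    summaries include tri-modal duration classification (ultra-short, short, long),
    Gaussian fits of the log-halfwidth distribution, event rates and rank-based
    group comparisons. A synthetic photon-counting movie and trace simulator with
    ground truth makes every stage testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    tiff,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'analysis.R'
    'events.R'
    'movie-io.R'
    'pipeline.R'
    'segmentation.R'
    'synthetic.R'
    'traces.R'
    'utils.R'
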