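Package: surfconn
Title: Vertex-Wise Short- and Long-Range White Matter Connectivity on
    Cortical Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps tractography streamline extremities onto a triangulated
    cortical surface and quantifies white matter connectivity at every
    vertex: mean tract length, short- and long-range connectivity indices
    with length-inverse streamline weighting, termination-proportion maps,
    and sulcal/gyral termination analyses.  Includes iterative
    nearest-neighbor surface smoothing calibrated to a target FWHM,
    vertex-wise general linear models with cluster detection and
    permutation-based cluster-wise correction, ICC/CV reliability maps,
    readers and writers for FreeSurfer binary surface/curv, GIFTI, OFF,
    TRK and TCK formats, and a synthetic-data generator (icospheres,
    folded sheets, streamline mixtures, multi-subject cohorts with
    planted group effects) so the whole pipeline is testable without any
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
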