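Package: mesoconn
Title: Cell-Class-Specific Mesoscale Connectome Estimation from Anterograde Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates cell-class-specific regionalized brain connectivity from
    anterograde viral tracing experiments. Implements Nadaraya-Watson kernel
    estimators that smooth jointly over 3D injection-centroid space and an
    abstract cell-class space (built from class-averaged regionalized
    projections), a nonnegative least-squares baseline, leave-one-out
    cross-validated model selection under a weighted l2-loss, assembly of
    class-specific source-by-target connectivity matrices with missing-value
    semantics, and decomposition of distal connectivity into sparse
    nonnegative archetypes via masked L1-penalized NMF with stability
    clustering. A synthetic tracing-data generator with known ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
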