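Package: vsreport
Title: Automated Imaging-Biomarker Measurement and Reporting for Vestibular Schwannoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardized linear and volumetric measurement of vestibular
    schwannoma from longitudinal intra-/extrameatal segmentation masks
    (NIfTI label volumes), including maximum in-plane tumour diameters by
    convex hull and rotating calipers, compartment volumes, meatal-axis
    directional extents, a diameter-selection algorithm for display to the
    clinical team, EAONO growth classification over a surveillance
    timeline, and deterministic summary/extended report rendering (HTML
    with inline SVG charts, STL surface meshes). A fully synthetic
    two-compartment phantom generator with analytic ground truth supports
    validation end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    optparse,
    withr,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
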