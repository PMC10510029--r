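Package: tdcsdir
Title: Cortical Current Direction Analysis for Transcranial Direct
    Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the direction of transcranial direct current
    stimulation (tDCS) current relative to cortical surface geometry.
    Builds a mid-grey-matter surface from pial and white-matter meshes,
    computes inner vertex normals, samples a volumetric electric-field
    vector image at surface vertices by nearest-neighbour lookup,
    and reports the per-vertex angle between inner normals and field
    vectors (0 degrees = radial inward, 90 = tangential, 180 = radial
    outward). Provides geodesic ring regions of interest on the sulcal
    bank and gyral crown, an electrode-location proxy for current
    direction, a synthetic folded-cortex cohort generator with analytic
    normals and point-source-pair fields, and cohort-level summary
    tables and proxy-versus-model correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
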