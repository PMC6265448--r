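Package: minihelix
Title: Reactive-Geometry Analysis of RNA Minihelix Aminoacylation Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for conformational ensembles of the
    aminoacylation reaction site of an RNA minihelix carrying an alanyl
    phosphate donor. Computes per-frame nucleophilic attack geometry
    (attack distance, Buergi-Dunitz, Flippin-Lodge and lobe angles,
    substrate-assisted-catalysis distances), classifies frames against a
    five-criterion definition of a reactive conformation, analyses backbone
    dihedral distributions and conformer groups that distinguish L- from
    D-alanine, compares per-run reactive counts with Welch's t-test, and
    provides an internal-coordinate synthetic ensemble generator that
    emulates the statistical structure of molecular-dynamics trajectories
    of the reaction site.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
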