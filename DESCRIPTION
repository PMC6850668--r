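Package: paircomm
Title: Paired Total (DNA) and Active (RNA) Amplicon Community Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing the 'total' (DNA-derived) and
    'active' (RNA-derived) fungal communities of paired soil samples.
    Provides OTU-table input/output with replicate pooling and singleton
    filtering, biogeographic range classification of OTUs (endemic,
    cosmopolitan, bipolar) from occurrence latitudes, iterated-rarefaction
    diversity metrics (richness, Pielou evenness, average taxonomic
    distinctness, k-dominance curves), a permutational paired sign test for
    differential abundance of OTU groups between nucleic-acid pools with an
    exact enumeration oracle, proportion-transformed Bray-Curtis distances
    with a one-factor permutational MANOVA, and a fully seeded synthetic
    paired-dataset generator with planted group effects for calibration and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
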