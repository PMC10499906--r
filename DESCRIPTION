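Package: ltpdigest
Title: In Vitro Gastrointestinal Digestion Analysis of the Peach Lipid
    Transfer Protein Pru p 3
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for analysing the in vitro
    gastrointestinal digestion of the peach allergen Pru p 3 and related
    non-specific lipid transfer proteins. Provides rule-based in silico
    proteolysis with trypsin/chymotrypsin/pepsin specificity, peptide
    monoisotopic and average mass calculation with post-translational
    modifications, disulphide-linked fragment connectivity analysis
    (reduced versus non-reduced observability), mapping of identified
    peptides onto protein isoforms with spectral-count abundance,
    sequence coverage, cleavage-site usage and linear IgE epitope
    survival classification, first-order digestion-kinetics fitting by
    Levenberg-Marquardt damped least squares with half-life and
    resistance testing, four-parameter logistic inhibition-ELISA IC50
    analysis with censoring, and a seeded synthetic-data generator that
    emulates densitometry time courses, peptide-identification tables
    and inhibition curves so the whole pipeline runs without wet-lab
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
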