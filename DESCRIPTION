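Package: phytoanchor
Title: Quantification of Phytoplankton Metabarcoding with Microscopy Anchors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts relative abundances of phytoplankton amplicon sequence
    variants (ASVs) into absolute abundance (cells per litre) and biomass
    (mg per litre) by anchoring them to total or class-specific microscopy
    counts, and assesses the consistency of the two methods. Provides
    microscopy-side tools (biovolume from cell geometry, biomass conversion,
    SEM-based splitting of cryptic species pairs, per-class anchor totals),
    ASV-side filtering and relative-abundance matrices, compositional
    transforms (centered log-ratio, rank scaling), diversity indices and
    rarefaction, Spearman correlation grids with Benjamini-Hochberg FDR
    control, complete-linkage heatmap ordering, co-inertia analysis with the
    RV coefficient, and a seeded generator of paired microscopy/metabarcoding
    communities with known ground truth and controllable amplification bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vegan,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'asv.R'
    'composition.R'
    'consistency.R'
    'generator.R'
    'microscopy.R'
    'quantification.R'
    'pipeline.R'
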