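Package: psamfit
Title: Biophysical Sequence-to-Affinity Models from Protein Binding
    Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers biophysically interpretable models of transcription
    factor DNA binding specificity from protein binding microarray (PBM)
    probe intensities. Binding free energies are modeled as sums over
    mononucleotide and adjacent-dinucleotide sequence features
    (position-specific affinity matrices and their feature-based
    extensions), estimated by robust block-wise iteratively reweighted
    least squares with trimming. The framework corrects for
    probe-positional and strand bias, supports an optional saturating
    intensity model with a non-specific binding term, detects palindromic
    motifs, selects motif length, and performs forward selection of
    multiple binding modes with relative association constants.
    Downstream utilities score promoter sequences by total binding
    affinity, test Gene Ontology association by rank-sum statistics, and
    fit a single-parameter occupancy saturation model to ChIP
    enrichments. A synthetic-data generator with known ground truth
    supports parameter-recovery validation of every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm,
    yaml
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'core.R'
    'fit.R'
    'genome.R'
    'io.R'
    'irls.R'
    'multimode.R'
    'psamfit-package.R'
    'refine.R'
    'seed.R'
    'simulate.R'
    'utils.R'
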