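Package: hicdecon
Title: Reference-Free Cell-Type Deconvolution of Bulk Hi-C Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell-type proportions and cell-type-specific chromatin
    contact profiles from multiple bulk Hi-C samples without reference
    profiles.  The estimator is a two-step non-negative matrix factorization
    (NMF): an initial factorization of the bin-pair by sample contact matrix,
    entropy- and variance-based selection of informative bin-pairs from the
    fitted profile matrix (applied separately to intrachromosomal and
    interchromosomal contacts), then a second factorization restricted to the
    informative bin-pairs whose column-normalized coefficient matrix gives the
    proportion estimates.  Includes contact-matrix assembly from long-format
    contact lists, insulation-score and A/B-compartment readouts, a
    single-cell Hi-C mixture simulator with known ground truth, permutation
    aware evaluation metrics, and post-hoc annotation of cluster-specific
    bin-pairs against epigenomic features.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
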