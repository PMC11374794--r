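Package: ffpesig
Title: Characterisation and Quantification of FFPE Artefacts in Cancer
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterise, quantify and subtract formalin-fixation
    (FFPE) and PCR artefacts in somatic variant calls from cancer whole-genome
    sequencing. Builds SBS96 substitution and ID83 indel mutational catalogues
    from VCF, fits non-negative signature exposures with bootstrap sparsity,
    subtracts known biological signatures and extracts recurrent artefact
    signatures from cohort residuals by stability-clustered KL-NMF, computes a
    per-sample FFPEimpact score from artefact exposures, normalises variant
    allele fractions by cancer cell content, and audits the clinical cost of
    naive VAF filtering against an actionable-gene panel. Ships a synthetic
    cohort generator (reference sequence, signature-driven variants with
    preparation-dependent VAF and burden structure, truth tables) so the whole
    pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    vcfR,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
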