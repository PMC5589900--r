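Package: imprintCNA
Title: Copy-Number-Aware Analysis of Imprinted DMR Methylation in Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the DNA methylation level implied by allele-specific
    copy number at imprinted differentially methylated regions (DMRs), calls
    genuine epimutations as deviations beyond three standard deviations of
    normal-tissue controls, classifies copy-number aberrations (copy-neutral
    LOH, internal versus telomere/centromere-bound), infers the parental
    origin retained through copy-neutral LOH, and scores genome-context
    hypermethylation burden (CIMP, bivalent domains, DNA methylation
    valleys). Includes an allele-resolved tumor-methylome simulator with
    known ground truth (segmental CNAs of known parental phase, injected
    epimutations, tumor-purity dilution, RRBS read counts) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
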