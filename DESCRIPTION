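Package: caddregions
Title: Region-Aware CADD Score Thresholds for Noncoding Variant Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives and applies genomic-region-specific thresholds for
    Phred-scaled deleteriousness scores (such as CADD) to prioritize noncoding
    variants in rare-disease genome analysis. Classifies variants into nine
    noncoding categories (upstream, downstream, 5'/3' UTR, intronic, splicing,
    ncRNA exonic/intronic, intergenic) from GTF or refGene gene models, fits
    per-region pathogenic-versus-benign score cutpoints by ROC analysis
    (Youden's J, F1, or a weighted blend) with Mann-Whitney U tests and
    Benjamini-Hochberg FDR correction, and filters whole-genome variant sets
    through an allele-frequency / region-threshold / de novo cascade. Includes
    a fully specified synthetic-data module emulating ClinVar-like, gnomAD-like
    and trio-WGS-like inputs so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    vcfR,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
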