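Package: snpmill
Title: SNP Discovery and Validation from Pooled Transcriptome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates SNP genotyping resources from pooled
    transcriptome sequencing of outbred species. Implements per-site
    pooled-sample SNP and indel probability calling with a one-sided
    binomial test at the composite-null boundary, Fisher combination of
    per-dataset probabilities, IUPAC masking of flanking variants in the
    reference, a multi-stage target-SNP filter cascade with Infinium
    array candidate selection, transcriptome-assembly quality evaluation
    (cross-species confidence classes, strand orientation inference,
    assembly statistics, contaminant screening), and genotyping-array
    locus QC (call rates, minor allele frequency, heterozygosity, exact
    Hardy-Weinberg test, conversion-rate extrapolation). A synthetic-data
    generator with planted ground truth makes the full pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
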