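Package: asmfam
Title: Allele-Specific DNA Methylation Analysis in Pedigrees from Simulated RRBS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reduced representation bisulfite sequencing (RRBS) of a
    three-generation pedigree with planted genotype-dependent, imprinted and
    CpG-disrupting methylation effects, and provides the full analysis chain to
    recover them: three-letter bisulfite-aware unique-best alignment, per-CpG
    methylation quantification, strand-aware SNP and genotype calling from
    bisulfite reads, Fisher-exact detection of allele-specific methylation with
    Storey q-value FDR control, pedigree-based parental-origin assignment and
    genotype-versus-imprinting classification, per-locus genotype-methylation
    linear models with held-out prediction and hierarchical clustering, and
    allele-specific-expression enrichment statistics (binomial, hypergeometric,
    Fisher and Wilcoxon tests over annotation tracks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    ape
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
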