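Package: emsmap
Title: Mapping EMS-Induced Mutants by Pooled-Sequencing Bulked Segregant
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for forward-genetic mapping of recessive mutations
    induced by ethyl methanesulfonate (EMS) mutagenesis using bulked
    segregant analysis of pooled whole-genome sequencing.  Implements a
    modified MutMap statistic: per-pool SNP-index (alternative-allele read
    fraction) for a wild-type pool and a mutant pool, its summed absolute
    divergence from the theoretical causal-locus values (1/3 and 1 for a
    recessive single-gene trait), threshold filtering, kernel-smoothed
    peak localization, and impact-aware candidate ranking.  Includes a
    synthetic-data generator emulating EMS mutagenesis (G:C to A:T
    transition bias), Mendelian segregation of a selfed heterozygote,
    phenotype-based pooling and pooled allele-depth sampling; a miniature
    strand-aware variant-effect annotator with HGVS output over toy gene
    models; Mendelian cross expectation and mutant-yield calculators; and
    plotting/report utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    ggplot2,
    grDevices,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
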