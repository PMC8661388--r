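Package: namqtl
Title: QTL Linkage Mapping for NAM and Biparental RIL Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics toolkit for maize-style nested association
    mapping (NAM) panels of recombinant inbred lines (RILs). Provides best
    linear unbiased estimates (BLUEs) of genotype values from augmented
    incomplete-block field trials via mixed models; single-family stepwise
    regression QTL mapping with permutation-derived genome-wide significance
    thresholds, total-percent-variance-explained (TPVE) accounting and 1-LOD
    support intervals; joint-linkage mapping across families with a family
    mean term and family-nested marker effects; Pearson trait correlation
    matrices with Holm familywise adjustment; HapMap genotype text I/O with
    numeric 0/1/2 recoding, minor-allele-frequency filtering and
    flanking-marker imputation; and a calibrated simulator of genetic maps,
    selfed RIL genotypes, additive traits and blocked field trials so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
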