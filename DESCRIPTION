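Package: deepenz
Title: Deep Enzymology Analysis of DNA Methyltransferase Specificity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of deep-enzymology hairpin bisulfite
    sequencing experiments that probe the flanking-sequence specificity of
    maintenance DNA methyltransferases such as DNMT1. The package generates
    randomized single-CpG and long patterned substrate libraries with known
    kinetic ground truth, reconstructs original molecules from hairpin
    bisulfite read pairs, fits per-NNCGNN-context monoexponential reaction
    progress curves to obtain methylation rate constants, derives
    observed/expected flanking preference profiles and pairwise substrate
    specificity ratios (hemimethylated vs unmethylated vs
    hemihydroxymethylated), compares enzyme variants, relates preference
    profiles to genomic CpG methylation via a randomization Z-test, and
    converts rate ratios into transition-state energy differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
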