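Package: wbha
Title: Covariate-Weighted False Discovery Rate Control for Genome-Wide
    Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Weighted multiple testing for genome-wide association scans.
    Implements the wBHa procedure: Benjamini-Hochberg step-up applied to
    p-values reweighted by a power function of an informative covariate
    (typically minor allele frequency), with the exponent chosen by grid
    search stabilized through bagging over bootstrap subsamples.  Also
    provides the unweighted BH and Storey-type q-value procedures, the
    fixed-weight wBH comparator, a genotype-phenotype simulator with
    Hardy-Weinberg discretization of block-equicorrelated latent Gaussians,
    single-marker association scans, and a replicated power/FDR evaluation
    harness with cluster-based counting for correlated markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
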