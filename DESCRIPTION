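Package: resyn
Title: Selection of Complementary Inbred Pairs to Resynthesize Heterozygous Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens ABH-coded genotypes of a selfing (F2) population derived
    from an elite, partly heterozygous individual and selects pairs of highly
    homozygous, genotypically complementary individuals whose cross would
    resynthesize the elite genotype.  Implements per-locus combination scoring
    with configurable score tables, heterozygosity and invariable-site filters,
    recombination-event counting on phased data, a deterministic parallel
    all-pairs engine, and a seeded F2 meiosis simulator (Haldane model) so the
    whole pipeline can be exercised without external data.  Results are tidy
    tibbles with broom-style tidy()/glance() methods and ggplot2 graphics.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
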