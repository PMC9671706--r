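Package: cernaxes
Title: Discovery of lncRNA-Associated ceRNA Axes in Case-Control Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for identifying long non-coding RNA
    (lncRNA) associated competing endogenous RNA (ceRNA) axes from case/control
    gene expression matrices. Implements quantile normalization, intensity and
    interquartile-range gene filtering, covariate adjustment, empirical-Bayes
    moderated two-group differential expression with Benjamini-Hochberg
    control, partitioning of differential genes into lncRNAs and mRNAs by
    symbol lists, construction of lncRNA-miRNA-mRNA candidate triples from
    curated interaction tables, sign-constrained Pearson co-expression gating
    with FDR control, protein-protein interaction overlay, and hypergeometric
    pathway over-representation analysis. Includes a synthetic-cohort
    generator with planted differential genes and planted ceRNA axes for
    end-to-end validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
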