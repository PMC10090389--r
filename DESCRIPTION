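Package: limlinker
Title: Disordered Linker Analysis for Tandem LIM-Domain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the intrinsically disordered linker that
    connects the two LIM domains of CSRP-family proteins and their homologs.
    Curates homolog hit tables and HMMER domain tables, classifies domain
    architectures, segments dual-LIM sequences into LIM1/linker/LIM2, and
    computes linker statistics: length distributions, a linker amino-acid
    propensity statistic, trimodal Gaussian-mixture classification of linker
    lengths, taxonomy frequency tables, and summaries of predicted
    post-translational modification sites at score cutoffs. Also provides
    geometric analyses of multi-model PDB trajectories (Kabsch superposition
    RMSD, per-residue RMSF, radius of gyration, interdomain distance density,
    phi-psi arrow maps, and a dihedral-based secondary-structure timeline),
    plus a synthetic-data generator that emulates every input with known
    ground truth.
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
    utils
Suggests:
    bio3d,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
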