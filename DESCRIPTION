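Package: pufapath
Title: Fatty-Acid Nomenclature, Desaturase/Elongase Reaction Modelling and
    LC-PUFA Biosynthesis Pathways in Sea Urchins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling long-chain polyunsaturated fatty acid
    (LC-PUFA) biosynthesis as characterized by heterologous expression of
    front-end desaturases (Fads) and elongases (Elovl), with the sea urchin
    Hemicentrotus pulcherrimus enzyme complement as the packaged reference
    dataset. Provides fatty-acid shorthand parsing and interconversion between
    delta and omega (n-x) nomenclature, classification of methylene-interrupted
    versus non-methylene-interrupted (NMI) unsaturation, desaturation and
    elongation reaction operators, reconstruction of the biosynthesis pathway
    graph from measured enzyme activities (including the 'delta-8 pathway' to
    arachidonic and eicosapentaenoic acid and the C20 NMI fatty-acid routes),
    the GC-FID conversion-percentage statistic from FAME peak areas,
    prediction of DMOX-derivative electron-ionization fragment series and
    inference of double-bond positions from observed spectra, motif-based
    classification of Elovl and Fads protein sequences, and seeded simulators
    for every input type.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
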