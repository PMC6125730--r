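Package: geoparth
Title: Individual-Based Simulation of Geographical Parthenogenesis Under
    Sexual Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the invasion of a sexual metapopulation by a dominant
    mutant allele for facultative parthenogenesis along an environmental
    productivity gradient. Individuals carry 21 diploid biallelic loci
    encoding polygenic male coercion, polygenic female resistance and the
    reproductive mode; generations are discrete, with coercion-threshold
    mating in Moore neighbourhoods, sexual (Mendelian) or automictic
    inheritance, nearest-neighbour dispersal between habitats, and
    density-dependent recruitment to a local carrying capacity. Includes
    replicated experiment drivers (parameter grids, robustness perturbations,
    Latin-hypercube sensitivity analysis), the Vargha-Delaney A effect size
    and Spearman partial rank correlations for analysing simulation output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
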