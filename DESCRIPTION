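Package: relsim
Title: Pedigree Simulation of Identity-by-Descent Segments with Crossover
    Interference and Sex-Specific Genetic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates relatives by transmitting founder haplotype segments
    through pedigrees under four crossover models: sex-specific or sex-averaged
    genetic maps crossed with the Housworth-Stahl two-pathway crossover
    interference model or a Poisson model.  Emits exact identity-by-descent
    (IBD) segments with IBD1/IBD2 types, kinship coefficients and degrees of
    relatedness, and can synthesize genotype data from phased input haplotypes
    with a configurable error and missingness model.  Ships closed-form
    renewal-process densities for IBD segment lengths under interference,
    including a finite-chromosome correction, an inhomogeneous-Poisson
    inter-crossover density for sex-specific maps, a censoring-aware maximum
    likelihood estimator of time since admixture from local ancestry tract
    lengths, and experiment drivers with bootstrap standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
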