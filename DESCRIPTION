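Package: cslmap
Title: Epistasis Mapping with Complete Chromosome Substitution Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for quantitative genetics with
    complete panels of chromosome substitution lines (CSLs). Provides genotype
    algebra for the full factorial 2^n panel, Monte-Carlo simulators of
    reverse-breeding (achiasmatic doubled-haploid production, near-isogenic and
    recombinant inbred line genotypes), a phenotype generator with block
    effects and smooth spatial field trends, mixed-model spatial adjustment
    with shrunken genotype means, a staged backward-elimination decomposition
    of chromosome main effects and two- and three-way epistasis under the
    marginality principle, and composite interval mapping with Li-Ji
    genome-wide thresholds and -log10(p)-drop support intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
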