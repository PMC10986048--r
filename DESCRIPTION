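Package: admixscan
Title: Windowed Genome Scans for Introgression, Haplotype Sharing and
    Selection in Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed population-genomic inference for admixed (hybrid-origin)
    populations with two ancestor panels and an outgroup: Patterson's D with
    weighted block-jackknife Z, windowed f_d introgression fractions with
    clamping rules, Weir-Cockerham Fst, nucleotide divergence d_xy, the
    population branch statistic (PBS) selection scan, an identity-by-descent
    sharing contrast (nIBD/rIBD/ZrIBD), local-ancestry window calling, and a
    gene-tree topology census tested against an incomplete-lineage-sorting
    coalescent null.  Includes a seeded cohort simulator that plants
    introgression tracts, selective sweeps and shared-haplotype tracts with
    truth intervals, exact half-open interval algebra, and end-to-end
    pipeline drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
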