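Package: haplocol
Title: Haplotype Networks and Sampling-Corrected Island Colonization Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for plastid-haplotype phylogeography of oceanic-island
    plants: collapsing aligned chloroplast loci into haplotypes (with
    inversion recoding and gaps treated as missing data), statistical
    parsimony haplotype networks, Nei-Tajima haplotypic diversity per
    island, exact minimum counts of inter-island colonization events on a
    rooted haplotype genealogy, and two-dimensional (field x genetic)
    rarefaction with accumulation-curve asymptotes to correct colonization
    counts for sampling effort. Includes a synthetic-data generator with
    known colonization histories for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
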