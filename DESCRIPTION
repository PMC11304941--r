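Package: magicphase
Title: Pedigree-Aware Phasing and Crossover Detection in Multiparental
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phases SNP genotypes of multiparental (MAGIC) populations
    descended from inbred founder lines using family-trio Mendelian
    segregation, infers grandparental haplotype origins, filters
    haploblocks by their number of informative alleles to guard against
    genotyping errors, and detects and classifies recombination events
    (crossovers and gene conversions). Includes a meiosis-level
    population simulator with known recombination truth and injected
    genotyping errors, and evaluation metrics (precision, recall, F1,
    resolution, Mendelian-error rates, error-rate calibration,
    per-interval crossover maps). Reads and writes PLINK PED/MAP flat
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
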