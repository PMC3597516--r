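Package: gaphdna
Title: Heteroduplex DNA Tract Analysis for Plasmid Gap-Repair Recombination
    Assays
Version: 0.1.0
Authors@R:
    person("gaphdna", "developers", email = "gaphdna@example.org",
           role = c("aut", "cre"))
Description: Calls heteroduplex-DNA (hDNA) tracts from per-SNP genotype codes
    of both alleles of individual noncrossover (NCO) gap-repair recombinants,
    classifies each event's molecular mechanism (synthesis-dependent strand
    annealing, double-Holliday-junction dissolution, Holliday-junction
    cleavage) from the hDNA topology, and decomposes normalized gap-repair
    efficiency into crossover/noncrossover and unidirectional/bidirectional
    class efficiencies. Includes a mechanistic event simulator that generates
    synthetic cohorts with the statistical structure the analysis assumes,
    plus pooled-variance Student's t and two-sided Fisher exact comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
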