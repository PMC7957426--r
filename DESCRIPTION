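Package: methribo
Title: Knockout-Controlled RNA m5C Calling and Ribosome Profiling Codon Occupancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for epitranscriptomic studies that
    pair RNA bisulfite sequencing with a methyltransferase-null genotype as a
    biological negative control. Implements reference preparation (CCA
    appending, merging of bisulfite-identical sequences), unique bisulfite-space
    read alignment, per-cytosine conversion pileups, deamination-rate
    estimation, threshold-based 5-methylcytosine site calling against the null
    genotype, and non-conversion threshold sweeps. A companion ribosome
    profiling module performs read-length periodicity gating, 12-nt P-site
    assignment, bulk codon occupancy with downstream-codon normalization,
    occupancy fold changes between genotypes, per-gene translation efficiency,
    codon-enrichment gene sets, stall profiles along transcripts, and polysome
    trace quantification. A built-in synthetic-data generator emits two-genotype
    bisulfite, ribosome-profiling and RNA-seq data with planted ground truth so
    every stage can be validated against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
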