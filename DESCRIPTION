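Package: DisorderMap
Title: Intrinsic Disorder and Missense Pathogenicity Profiling of Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to profile intrinsic disorder along a protein sequence and
    relate it to predicted missense pathogenicity. Reads per-residue disorder
    predictor outputs, AlphaMissense-style variant score tables, FuzDrop-style
    droplet-promoting probability profiles, STRING-style weighted edge lists
    and AlphaFold structure models; builds consensus mean disorder profiles
    (MDP) with PPDR classification, aggregates variant pathogenicity to
    per-residue tracks, fits an exponential-decay model between disorder and
    smoothed pathogenicity, extracts threshold-run regions (disordered regions
    and droplet-promoting regions), computes amino-acid composition enrichment
    with resampling-based significance, summarises interaction networks, and
    repaints structure B-factors with any per-residue track. A seeded
    synthetic-data generator produces every input format with known ground
    truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    bio3d,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
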