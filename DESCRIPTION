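Package: setphen
Title: Deep Computational Phenotyping of SET-Domain Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multidimensional computational phenotyping of
    missense variants in protein domains, developed around the SET catalytic
    domain of histone H3K4 methyltransferases (KMT2C/KMT2D). Covers parsing and
    summary of clinical variant tables under the five-tier significance system,
    paralog annotation by alignment position mapping with an
    already-substituted exclusion rule, per-tool pathogenicity consensus
    calling, threshold classification of folding/binding free-energy changes
    and residue frustration indices, a decoy Z-score frustration engine,
    molecular-dynamics trajectory metrics (RMSD, RMSF, radius of gyration,
    Shrake-Rupley SASA, hydrogen-bond occupancy), MM-PBSA binding free-energy
    aggregation with pairwise nonbonded interaction energies, and an
    integrative structural/dynamic molecular-fitness classifier (SV/DV/SDV).
    Includes seeded synthetic-data generators for every input class so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
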