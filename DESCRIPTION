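Package: semadimer
Title: Structural Analysis of Semaphorin Dimerization and Receptor-Binding
    Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative structural analysis of semaphorin ectodomains:
    buried-surface accounting at homo- and heterodimer interfaces including
    N-glycan contributions, interchain disulfide detection and covalent-dimer
    calls, rigid-body superposition with iterative core trimming, inter-domain
    hinge angles and ensemble RMSF, affine-gap sequence alignment with
    N-glycosylation sequon scanning, transfer of a receptor-binding interface
    onto query structures with class-specific substitution (hot-spot) calling,
    structure-based phylogeny from superposition distances, 1:1 equilibrium
    binding (Kd) fitting with ligand depletion and bootstrap uncertainty, and
    oligomeric-state assignment from light-scattering molar masses.
    Seed-controlled synthetic generators provide structures, sequence
    families, titrations and molar-mass observations with planted features so
    the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    phangorn,
    Rcpp,
    seqinr,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
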