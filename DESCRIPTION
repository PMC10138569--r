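Package: structvar
Title: Structural Impact Assessment of Missense Variants in Protein Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for assessing the structural and pathogenic
    impact of missense variants on protein structures. Provides in-silico
    mutagenesis with a rotamer library, geometric feature extraction (steric
    clashes, hydrogen bonds, salt bridges, disulfides, ligand contacts,
    solvent accessibility, glycosylation sequons, helix-breaking prolines),
    Kabsch superposition with RMSD and TM-score, stability (ddG)
    classification, predictor consensus, allele-frequency evidence, ACMG/AMP
    computational evidence codes (PP3/BP4/PM2), and splice-consequence
    simulation.  Ships a curated 30-variant ABCA4 reference cohort and
    synthetic structure generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
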