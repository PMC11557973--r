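Package: membind
Title: Peptide-Membrane Binding Analysis from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Maintainer", "membind", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies peptide-membrane bound and unbound states in molecular
    dynamics trajectories using an atom-contact criterion with a persistence
    filter, computes residence-time binding free energies from the bound and
    unbound time totals, profiles peptide-lipid contacts per residue and per
    lipid species, and quantifies the free-energy shift caused by fluorophore
    labelling via ordinary least squares regression of labelled against native
    binding free energies. Includes a synthetic trajectory generator with a
    two-state Markov binding process that provides ground truth for validating
    every analysis stage, plus readers and writers for GRO and multi-model PDB
    coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
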