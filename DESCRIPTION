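Package: dockhb
Title: Post-Docking Hydrogen-Bond and Pose-Cluster Analysis for
    Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("dockhb", "maintainers", email = "dockhb@example.org",
           role = c("aut", "cre"))
Description: Analyses minimized docking poses of enzyme-inhibitor
    complexes. Reads fixed-column PDB structures (including multi-model
    pose ensembles with a sidecar energy table), partitions atoms into
    ligand, protein, water and ion roles, and detects protein-ligand and
    water-ligand hydrogen bonds with a geometric criterion
    (hydrogen-acceptor distance below 3.5 Angstrom, donor-hydrogen-
    acceptor angle between 120 and 170 degrees). Clusters pose ensembles
    by RMSD with lowest-energy coverage selection, summarises bonds per
    pose and mean bond distance per ligand in vacuum and with binding
    site waters, supports a focused survey of a ligand acetyl oxygen
    against a catalytic-site glutamine and named waters, and compares
    active against low-active inhibitor classes with Welch's t-test.
    Ships a typed activity table (IC50, HARBS, TNF-alpha, CaCo-2, MNED)
    with pIC50, selectivity and potency-filter helpers, plus a synthetic
    binding-pocket generator with planted hydrogen-bond geometry for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
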