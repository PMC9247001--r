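Package: methylwalk
Title: Structure-Based Assignment of Methyl-TROSY Spectra with NOE Networks and Paramagnetic Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assigning [13C,1H3]-methyl resonances of large,
    selectively methyl-labeled proteins from crystal structures and NMR
    restraints. Implements residue-type classification from selectively
    labeled samples, NOE-network construction from 4D HMQC-NOESY-HMQC
    cross-peak lists, Metropolis Monte Carlo peak-to-methyl assignment with
    consensus over trials, cut-off scanning and two-state combination,
    pseudocontact-shift (PCS) delta-chi tensor fitting with movable metal
    position and bootstrap errors, Solomon-Bloembergen-Morgan paramagnetic
    relaxation enhancement (PRE) modelling with ensemble metal-position
    fitting, a four-state protein/ligand/metal binding-equilibrium solver
    for paramagnetic sample design, and a ground-truthed synthetic data
    generator covering every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
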