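Package: glycograft
Title: Glycan Conformer Libraries and Steric Grafting onto Protein
    Glycosylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reducing multi-replica conformational ensembles of
    glycans to weighted libraries of representative three-dimensional
    conformers (pairwise-distance featurization, principal component
    reduction, Gaussian-mixture clustering with silhouette-guided model
    selection and kernel-density representative extraction), and for
    grafting those conformers onto protein glycosylation sites by
    steric-loss minimization with a genetic algorithm over the linkage
    torsions and a stochastic torsion-refinement fallback. Includes
    N-sequon occupancy scanning with a single-GlcNAc probe, the Asn
    amide OD1/ND2 swap utility, multi-frame ensemble fitting for glycan
    exclusion-volume estimation, and a native Shrake-Rupley solvent
    accessible surface area implementation. All test inputs are built by
    deterministic synthetic-structure generators; no downloads required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    mclust,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'utils.R'
    'kde.R'
    'gap.R'
    'pdb-io.R'
    'graph.R'
    'linkage.R'
    'fixtures.R'
    'library-io.R'
    'sasa.R'
    'fitness.R'
    'ga.R'
    'wiggle.R'
    'graft.R'
    'ensemble.R'
    'sequon.R'
    'cli.R'
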