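Package: siteclust
Title: Active-Site Signature Extraction and Clustering for Enzyme Families
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies enzyme family members into putative isofunctional
    groups from the residues lining their active-site pocket. A reference
    pocket is defined from a P2RANK prediction file, from ligand proximity in
    a holo structure, or from a user-supplied residue list; pocket positions
    are mapped through pairwise structural alignments (3D mode) or a multiple
    sequence alignment (2D mode) to give one fixed-length active-site string
    per member. All pairs of site strings are scored with a physicochemical
    amino-acid distance matrix and clustered by density (DBSCAN on the
    precomputed distances) with automatic parameter selection, size-ordered
    cluster numbering and optional re-clustering of individual groups.
    Clusters are summarised as position frequency matrices, information
    content profiles and consensus sites, and 2D- and 3D-derived sites can
    be compared member by member. A synthetic-family generator provides
    fully self-contained fixtures with planted groups.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    cluster,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    igraph
Config/testthat/edition: 3
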