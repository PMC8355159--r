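Package: IghClonal
Title: Clonal Landscape Analysis of IgH B-Cell Receptor Repertoires
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers B-cell clones from annotated immunoglobulin heavy-chain
    (IgH) rearrangements and summarises the clonal landscape of sorted B-cell
    subsets. Clones are defined by shared V gene, J gene and CDR3 length with
    at least 85 percent CDR3 amino-acid identity (single-linkage), followed by
    collapsing of clones whose consensus CDR3 nucleotide sequences lie within
    2 nucleotides of each other to absorb erroneous gene calls. Provides
    per-subset repertoire statistics (D20 clonality index, replicate-library
    Jaccard overlap, somatic hypermutation fractions, CDR3 length
    distributions, VH gene usage), cross-subset clonal overlap measures
    (Jaccard, clone-size-weighted cosine, Venn region counts, presence
    tracks), AIRR Rearrangement TSV input/output, and a synthetic repertoire
    generator with ground-truth clone labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'IghClonal-package.R'
    'clone_inference.R'
    'pipeline.R'
    'repertoire_io.R'
    'repertoire_metrics.R'
    'simulate.R'
    'subset_overlap.R'
    'utils.R'
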