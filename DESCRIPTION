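Package: PathCompare
Title: Systematic Comparison and Reconciliation of Metabolic Pathway Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Entity resolution and agreement statistics for human metabolic
    pathway databases. Resolves genes, EC numbers, metabolites and reactions
    across two or more database snapshots using an identifier cascade
    (primary compound identifier, secondary identifiers, normalized name plus
    chemical formula) with transitive closure, matches reactions modulo
    direction, compartment and configurable currency species (electrons,
    protons, water), and computes consensus, majority, unique and pairwise
    overlap statistics, category-restricted comparisons and single-pathway
    case studies. Includes a synthetic database generator that derives
    perturbed snapshots from a common ground truth (coverage subsetting,
    identifier dropout, name variants, protonation shifts, reaction lumping,
    alternative cosubstrates, generic-metabolite substitution, obsolete
    identifiers, direction flips, proton/water balancing differences) with
    full truth bookkeeping, so recovery of the known overlap can be tested.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'snapshot.R'
    'io.R'
    'updates.R'
    'expand.R'
    'matchconfig.R'
    'matching.R'
    'reactions.R'
    'genes_ec.R'
    'stats.R'
    'combinations.R'
    'categories.R'
    'restricted.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
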