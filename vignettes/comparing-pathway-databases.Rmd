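---
title: "Comparing metabolic pathway databases with PathCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing metabolic pathway databases with PathCompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PathCompare)
```

## The problem

Several groups maintain descriptions of the human metabolic network, built
with different reconstruction philosophies: genome-annotation-driven,
incremental and reaction-centric, flux-model-oriented, or automatically
derived and partially curated. A researcher choosing one of them inherits
its coverage decisions and its conventions, and analyses run against
different databases can disagree. PathCompare quantifies how much N such
databases agree — per gene, EC number, metabolite and reaction — and is
equally a test bed for *why* they disagree, via a synthetic generator that
plants known causes of divergence and a ledger that records the planted
truth.

## Entity resolution

### Metabolites: the identifier cascade

Two metabolite records are compared with `metabolitesMatch()`:

1. **Override pairs** (hand-curated equivalences) force a match first.
   They exist because some pairs that refer to the same chemistry carry
   different primary identifiers on purpose — typically an enzyme-bound
   versus free form of a cofactor — and no automated rule should guess at
   them.
2. **Generic/specific guard**: a class placeholder ("an alcohol") never
   matches a specific compound ("ethanol"). Class records are still
   compared with each other, and their listed instances participate in the
   comparison as ordinary records.
3. **Primary compound identifier** (KEGG-Compound-style): if both records
   carry one, equality decides and the cascade stops. A disagreeing primary
   identifier blocks the match even when secondary identifiers agree — the
   primary namespace is the curated common ground, and the override
   mechanism exists precisely for its exceptions.
4. **Secondary identifiers** (KEGG Glycan, ChEBI, PubChem Compound, CAS):
   any namespace present on both and equal gives a match. We deliberately
   require only one agreeing namespace; conflicting additional namespaces
   are a curation signal, not a veto.
5. **Name + formula**: a shared normalized name — lowercased, Unicode
   compatibility form, all whitespace/punctuation removed, no
   transliteration (`normalizeName()`) — matches only if both records carry
   a chemical formula and the formulas agree element-for-element. A record
   with no formula cannot satisfy a requirement, so it cannot match by
   name; this is the conservative reading, chosen because synonym lists are
   the least reliable evidence. With `h_tolerant_formula = TRUE` the
   hydrogen count is disregarded, absorbing protonation-state conventions
   (databases store metabolites at different assumed pH).

Names are multi-valued and any shared normalized synonym counts, with one
ambiguity guard: a normalized name attached to more than one distinct
formula *within a single snapshot* is quarantined from name matching
entirely (and reported). Without the guard one promiscuous synonym can
weld unrelated compounds into a single class through transitive closure.

Pairwise matches are an observation, not yet an identity: identity is the
transitive closure, computed with a union–find over all candidate pairs
(within and across snapshots). Candidates are generated by blocking on
each identifier value, each normalized name and each override descriptor;
since every cascade route requires one of those shared keys, the blocked
closure provably equals the all-pairs closure, which the test suite
verifies against an independent brute-force + graph-components oracle on
randomized fixtures. Class representatives are the lexicographically
smallest member keys, so results are deterministic and order-independent.

### Reactions

A reaction's identity is its pair of participant class-sets
(`reactionSignature()`): direction is ignored (the same conversion is
written in either direction), compartments are ignored, and stoichiometric
coefficients are stored but deliberately ignored — databases document
unbalanced reactions, and balancing disagreements must not block matches.
In *relaxed* mode (the default `matchConfig()`), electrons, protons and
water are removed from both sides before comparison, because reactions are
most often unbalanced with respect to exactly those species; *strict* mode
(`ignore_metabolites = character(0)`) keeps them. A single-pathway case
study conventionally ignores protons only. The ignore set is resolved to
metabolite classes via primary identifiers and names, so it follows
whatever the partition knows about those species.

A reaction whose two sides collapse to the same class-set after removal
(e.g. pure transport of water between compartments under relaxed matching)
retains no comparable content; it is flagged *degenerate*, excluded from
the countable statistics, and listed with its reason in reports. Within a
snapshot, a conversion written in both directions falls into one class and
is counted once.

### Genes and EC numbers

Genes are compared on the single shared identifier namespace (Entrez-style
digit strings); no distinction is made between a gene encoding a complete
catalyst and one encoding a complex component, because only some databases
model complexes syntactically. Records with no identifier are excluded and
reported. EC numbers are compared complete (level 4) or on their first
three components (level 3, "same type of enzymatic function"); partial
numbers such as `1.1.1.-` are semantically ambiguous and excluded at both
levels.

### Out-of-date identifiers

`applyIdentifierUpdates()` replaces transferred identifiers with their
terminal targets and removes obsolete ones. Removal deletes the
*identifier*, never the record: the entity remains comparable through its
other routes. Transfer maps are required pre-flattened, which makes the
operation idempotent. The synthetic module ships matching update tables so
this path is exercisable offline.

### Set/class reactions

Databases that write reactions over metabolite classes or sets are
instantiated with `expandGenericReactions()`: in `first_member` mode the
first listed instance of each class is substituted, pairing the k-th class
on the left with the k-th on the right; `all_members` emits one reaction
per member index up to the shortest instance list. When the two sides
carry unequal numbers of instantiable classes the positional pairing is
ill-defined and the reaction is left unexpanded and flagged rather than
guessed at — mirroring the handful of uninstantiable cases real exports
contain. Classes with no recorded instances stay in place (flagged), and
instances remain ordinary metabolite records in either mode.

## Agreement statistics

For each entity class, `consensus()` computes over identity classes the
union size, the occurrence histogram (classes present in exactly k of N
snapshots), the N-way consensus as a percentage of the union, the majority
score (≥ k snapshots, default k = 3 — "more databases agree than
disagree" for five inputs; capped at N), and unique counts. All printed
percentages use **round-half-up to whole percent**. The rounding convention
is not stated by the published comparison this package models itself on; we
adopt round-half-up because it is the single convention that reproduces
every percentage printed there from its printed count/union pair (the test
suite asserts all of them), and flag that this is our inference, not the
original authors' stated intent.

`pairwiseTable()` is the two-way set formula; `pairwiseCompare()`
additionally **rebuilds the partition for each pair**, because transitive
closure through a third database may bridge two records that share no
direct evidence — a pairwise number computed on the N-way partition would
overstate pairwise agreement.

The combination analyses operate on the consensus entities:
`combinationGeneEC()` classifies each consensus gene by whether all
snapshots attach the same complete-EC set to it, share at least one EC
number, or none. `combinationReactionGeneEC()` does the same per consensus
reaction class, where a class's gene/EC set per snapshot is the union over
that snapshot's member reactions (members collapsed into one class are one
reaction written differently, so their annotations pool). A class whose
gene disagreement consists of supersets of a shared core that at least one
snapshot reports exactly is tagged `additional_genes` — our operational
rendering of "some database links extra genes"; disagreements where every
snapshot both adds and lacks genes are left untagged as genuinely
conflicting.

## Categories and restricted comparisons

Pathways are assigned one of eleven category labels (nine
metabolism categories modeled on the KEGG hierarchy, plus `miscellaneous`
and `transport`) from a user-supplied mapping table; reactions — and
through them genes and EC numbers — inherit the categories of *all* their
pathways. A reaction is `transport` when its participants span more than
one compartment; records with no compartment annotation share one
"unspecified" pseudo-compartment, so sparsely annotated snapshots are not
spuriously full of transport. `coreSubset()` keeps reactions carrying at
least one of six core categories (amino acid, carbohydrate, energy, lipid,
cofactors-and-vitamins, nucleotide metabolism), drops transport and —
per-snapshot, configurable — macromolecular reactions (any participant
flagged protein). Reactions in no pathway have no category and drop out of
the core comparison; reactions mapped only to `miscellaneous` are likewise
excluded from the core denominators, which we document as our choice where
the original table semantics are ambiguous. `restrictedCompare()` re-runs
the full four-level comparison on a pathway scope (with per-snapshot
aliases, since databases name pathways differently) or a category scope.

## The synthetic generator

`generateGroundTruth()` builds the reference network the study conditions
are defined on: pathways partition the reactions into linear conversion
chains over unique main metabolites; every reaction turns over one of four
cofactor pairs (ATP/ADP, NAD⁺/NADH, NADP⁺/NADPH, FAD/FADH₂) so currency
metabolites are hubs by construction; protons, water and phosphate appear
on regular subsets of reactions so the strict/relaxed distinction has
content; a few ATP-driven transport reactions move a metabolite between
compartments; generic classes with instance lists and protein-flagged
participants are planted at low rates; and every chain of three
consecutive reactions is an annotated lumpable route. Every metabolite
carries a full identifier bundle in a synthetic accession namespace, a
unique name and a unique formula (unique hydrogen counts), which is what
makes exact recovery provable: under perturbations that leave names and
formulas intact, no false merge is possible.

`deriveSnapshot()` applies a `perturbationProfile()` to the truth. Each
probability acts independently per eligible entity; defaults are all zero
(with full coverage), so the default profile is the identity up to
local-id relabeling — relabeling guarantees nothing can match on local
ids. The perturbations emulate, one cause each, the documented sources of
database disagreement: coverage subsetting; per-namespace identifier
dropout; name variants (half recoverable case/punctuation edits that
normalization must undo, half "hard synonyms" that are deliberately
unrecoverable, exercising the missing-match paths); protonation shifts
that move one hydrogen in the formula *and* tag the name, so
`h_tolerant_formula` has an observable effect; lumping of a fully covered
route into its symbolic net reaction (intermediates canceled); an
alternative-cosubstrate duplicate (ATP/ADP swapped to ITP/IDP, emitted as
an additional reaction with its own truth identity, as real databases list
alternative substrates as separate reactions); generic-class substitution;
obsolete-identifier injection (repairable via the shipped update tables);
direction flips; one-sided H⁺/H₂O balancing edits; and pathway-assignment
dropout. The `TruthLedger` maps every emitted entity to its truth identity
(lumped reactions to their route id) with the tags applied, so
`trueOverlap()` yields the exact overlap a perfect matcher would recover,
independent of the matcher.

What the generator does **not** emulate: chemical realism beyond
currency-metabolite structure (formulas are synthetic), thermodynamics or
mass balance after lumping with alternative substrates, correlated
curation (real databases copy from each other; derived snapshots are
conditionally independent given the truth), and cross-database synonym
vocabularies richer than the planted pools. Passing recovery tests
therefore demonstrates the correctness of the resolution machinery under
the planted causes, not that real 2011-era database dumps would reproduce
any particular published count — those depend on the snapshots themselves.

## Numerical and engineering choices

* Determinism everywhere: sorted canonical serialization, lexicographic
  class representatives, no randomness in matching; `runPipeline()` and
  `simulateSnapshots()` produce byte-identical artifact directories for
  identical config and seed (run logs carry versions, never timestamps).
* The interchange format is this package's own (one JSON document per
  snapshot, or a TSV bundle for hand-authored fixtures), with a versioned
  schema in `inst/extdata/`. SBML/BioPAX import is explicitly refused with
  a pointer to the interchange format; source-specific exports are out of
  scope.
* Stoichiometry is stored but never part of reaction identity (flagged
  above); gene identifiers are expected pre-stripped of transcript-variant
  suffixes.
* Degenerate inputs: empty reaction sides are rejected at load; an empty
  union is an error for percentage statistics (undefined), and entity
  classes with an empty union are skipped by `compareSnapshots()`.
* Test problem sizes: the oracle-equivalence suite runs 100 randomized
  fixtures of three 14-record snapshots against the brute-force closure;
  recovery fidelity uses 20 seeds of a 40-reaction truth with three
  derived snapshots; the closed-form check uses 50 seeds of a 120-reaction
  truth. These sizes give stable statistics while keeping the default test
  run fast; all of them are ordinary parameters of the fixtures, not
  limits of the method.

## Limitations

* No structural (InChI/SMILES) comparison and no fuzzy name matching; both
  are deliberate non-goals, as is automated alignment of lumped multi-step
  conversions — the package detects and plants lumping synthetically but
  does not try to discover step correspondences in real data.
* The consensus is sensitive to the number and size of databases compared;
  the pairwise and majority statistics are provided precisely because the
  N-way consensus alone is a blunt instrument.
* Name quarantine is per-snapshot: a synonym ambiguous only *across*
  snapshots still matches (by design — with a formula requirement as the
  backstop).
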