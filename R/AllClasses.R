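#' @import methods
NULL

# ---- column templates -------------------------------------------------------

emptyGenes <- function() {
  data.frame(local_id = character(0), gene_id = character(0),
             stringsAsFactors = FALSE)
}

emptyMetabolites <- function() {
  df <- data.frame(
    local_id = character(0), formula = character(0), charge = integer(0),
    compartment = character(0), kegg_compound = character(0),
    kegg_glycan = character(0), chebi = character(0),
    pubchem_compound = character(0), cas = character(0),
    is_generic = logical(0), is_protein = logical(0),
    stringsAsFactors = FALSE
  )
  df$names <- list()
  df$instance_ids <- list()
  df
}

emptyReactions <- function() {
  df <- data.frame(
    local_id = character(0), reversible = logical(0),
    is_set_reaction = logical(0), expansion_flagged = logical(0),
    stringsAsFactors = FALSE
  )
  df$side_a <- list()
  df$side_b <- list()
  df$genes <- list()
  df$ecs <- list()
  df$pathways <- list()
  df
}

emptyPathways <- function() {
  data.frame(local_id = character(0), name = character(0),
             category = character(0), stringsAsFactors = FALSE)
}

#' Canonical pathway category vocabulary
#'
#' Nine metabolism categories modeled on the KEGG pathway hierarchy, plus
#' \code{"miscellaneous"} for pathways fitting none of them and
#' \code{"transport"} for transport pathways. This closed vocabulary is the
#' only legal content of the \code{category} column of a snapshot's pathway
#' table.
#'
#' @return Character vector of the eleven category labels.
#' @seealso [coreCategories()] for the six labels forming core metabolism.
#' @export
categoryLabels <- function() {
  c("amino acid metabolism", "carbohydrate metabolism", "energy metabolism",
    "glycan biosynthesis and metabolism", "lipid metabolism",
    "metabolism of cofactors and vitamins",
    "metabolism of secondary metabolites", "nucleotide metabolism",
    "xenobiotics biodegradation and metabolism", "miscellaneous", "transport")
}

#' Core metabolism categories
#'
#' The six categories retained when a comparison is restricted to core
#' metabolic processes: amino acid, carbohydrate, energy, lipid, cofactors
#' and vitamins, and nucleotide metabolism.
#'
#' @return Character vector of six category labels.
#' @export
coreCategories <- function() {
  c("amino acid metabolism", "carbohydrate metabolism", "energy metabolism",
    "lipid metabolism", "metabolism of cofactors and vitamins",
    "nucleotide metabolism")
}

ecPattern <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$"

# ---- DatabaseSnapshot -------------------------------------------------------

#' DatabaseSnapshot: one pathway database's content
#'
#' Container for the genes, metabolites, reactions and pathways of one
#' pathway-database snapshot, with referential integrity enforced by the
#' validity method. Build instances with [databaseSnapshot()] or load them
#' from the interchange format with [readSnapshot()].
#'
#' @slot name Snapshot (database) name, unique within a comparison.
#' @slot genes data.frame with columns \code{local_id}, \code{gene_id}
#'   (shared-namespace digit string, \code{NA} when absent).
#' @slot metabolites data.frame with scalar columns \code{local_id},
#'   \code{formula}, \code{charge}, \code{compartment}, the identifier bundle
#'   (\code{kegg_compound}, \code{kegg_glycan}, \code{chebi},
#'   \code{pubchem_compound}, \code{cas}), flags \code{is_generic},
#'   \code{is_protein}, and list columns \code{names} (synonyms, >= 1) and
#'   \code{instance_ids} (members of a generic class).
#' @slot reactions data.frame with columns \code{local_id},
#'   \code{reversible}, \code{is_set_reaction}, \code{expansion_flagged} and
#'   list columns \code{side_a}/\code{side_b} (named numeric vectors:
#'   metabolite local_id -> stoichiometric coefficient), \code{genes},
#'   \code{ecs}, \code{pathways}.
#' @slot pathways data.frame with columns \code{local_id}, \code{name},
#'   \code{category} (one of [categoryLabels()] or \code{NA}).
#' @aliases DatabaseSnapshot
#' @export
setClass("DatabaseSnapshot",
  representation(name = "character", genes = "data.frame",
                 metabolites = "data.frame", reactions = "data.frame",
                 pathways = "data.frame"),
  prototype(name = "snapshot", genes = emptyGenes(),
            metabolites = emptyMetabolites(), reactions = emptyReactions(),
            pathways = emptyPathways())
)

validSnapshot <- function(object) {
  msgs <- character(0)
  g <- object@genes; m <- object@metabolites
  r <- object@reactions; p <- object@pathways
  if (length(object@name) != 1 || is.na(object@name) || !nzchar(object@name))
    msgs <- c(msgs, "snapshot name must be a single non-empty string")
  for (nm in c("genes", "metabolites", "reactions", "pathways")) {
    ids <- slot(object, nm)$local_id
    if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicated local_id in %s: %s", nm,
                              joinSet(ids[duplicated(ids)])))
  }
  bad_gene <- !is.na(g$gene_id) & !grepl("^[0-9]+$", g$gene_id)
  if (any(bad_gene))
    msgs <- c(msgs, sprintf("gene_id must be a digit string: %s",
                            joinSet(g$gene_id[bad_gene])))
  if (nrow(m) > 0) {
    nn <- vapply(m$names, length, integer(1))
    if (any(nn == 0))
      msgs <- c(msgs, sprintf("metabolite without any name: %s",
                              joinSet(m$local_id[nn == 0])))
    self_inst <- mapply(function(id, inst) id %in% inst,
                        m$local_id, m$instance_ids)
    if (any(self_inst))
      msgs <- c(msgs, sprintf("metabolite lists itself as instance: %s",
                              joinSet(m$local_id[self_inst])))
    inst_not_generic <- vapply(m$instance_ids, length, integer(1)) > 0 &
      !m$is_generic
    if (any(inst_not_generic))
      msgs <- c(msgs, sprintf(
        "instance_ids present but is_generic is FALSE: %s",
        joinSet(m$local_id[inst_not_generic])))
    dangling <- setdiff(unique(unlist(m$instance_ids)), m$local_id)
    if (length(dangling))
      msgs <- c(msgs, sprintf("instance_ids reference unknown metabolites: %s",
                              joinSet(dangling)))
  }
  if (nrow(r) > 0) {
    for (side in c("side_a", "side_b")) {
      sides <- r[[side]]
      empt <- vapply(sides, length, integer(1)) == 0
      if (any(empt))
        msgs <- c(msgs, sprintf("empty %s in reaction(s): %s", side,
                                joinSet(r$local_id[empt])))
      dup <- vapply(sides, function(s) anyDuplicated(names(s)) > 0,
                    logical(1))
      if (any(dup))
        msgs <- c(msgs, sprintf(
          "metabolite repeated on one side of reaction(s): %s",
          joinSet(r$local_id[dup])))
      nonpos <- vapply(sides, function(s) any(s <= 0), logical(1))
      if (any(nonpos))
        msgs <- c(msgs, sprintf(
          "non-positive coefficient in %s of reaction(s): %s", side,
          joinSet(r$local_id[nonpos])))
    }
    refmet <- unique(unlist(lapply(c(r$side_a, r$side_b), names)))
    dang <- setdiff(refmet, m$local_id)
    if (length(dang))
      msgs <- c(msgs, sprintf("reactions reference unknown metabolites: %s",
                              joinSet(dang)))
    dangg <- setdiff(unique(unlist(r$genes)), g$local_id)
    if (length(dangg))
      msgs <- c(msgs, sprintf("reactions reference unknown genes: %s",
                              joinSet(dangg)))
    dangp <- setdiff(unique(unlist(r$pathways)), p$local_id)
    if (length(dangp))
      msgs <- c(msgs, sprintf("reactions reference unknown pathways: %s",
                              joinSet(dangp)))
    ecs <- unique(unlist(r$ecs))
    badec <- ecs[!grepl(ecPattern, ecs)]
    if (length(badec))
      msgs <- c(msgs, sprintf("malformed EC number(s): %s", joinSet(badec)))
  }
  if (nrow(p) > 0) {
    badcat <- !is.na(p$category) & !(p$category %in% categoryLabels())
    if (any(badcat))
      msgs <- c(msgs, sprintf("unknown pathway category: %s",
                              joinSet(p$category[badcat])))
  }
  if (length(msgs)) msgs else TRUE
}

setValidity("DatabaseSnapshot", validSnapshot)

# ---- UpdateTables -----------------------------------------------------------

#' UpdateTables: identifier transfer and obsolescence tables
#'
#' Per-namespace maps of out-of-date identifiers. \code{transferred} maps an
#' old identifier to its current replacement (pre-flattened: targets are
#' terminal, never themselves keys); \code{obsolete} lists identifiers that
#' were retired with no replacement. Namespaces are \code{gene}, \code{ec}
#' and the five metabolite identifier namespaces.
#'
#' @slot transferred Named list: namespace -> named character vector
#'   (old -> new).
#' @slot obsolete Named list: namespace -> character vector of retired ids.
#' @aliases UpdateTables
#' @export
setClass("UpdateTables",
  representation(transferred = "list", obsolete = "list"),
  prototype(transferred = list(), obsolete = list())
)

setValidity("UpdateTables", function(object) {
  msgs <- character(0)
  spaces <- union(names(object@transferred), names(object@obsolete))
  for (ns in spaces) {
    tr <- object@transferred[[ns]] %||% character(0)
    ob <- object@obsolete[[ns]] %||% character(0)
    clash <- intersect(names(tr), ob)
    if (length(clash))
      msgs <- c(msgs, sprintf(
        "namespace %s: id(s) both transferred and obsolete: %s",
        ns, joinSet(clash)))
    chain <- intersect(unname(tr), names(tr))
    if (length(chain))
      msgs <- c(msgs, sprintf(
        "namespace %s: transfer targets are themselves keys (flatten first): %s",
        ns, joinSet(chain)))
  }
  if (length(msgs)) msgs else TRUE
})

# ---- MatchConfig ------------------------------------------------------------

#' MatchConfig: parameters of the entity-resolution cascade
#'
#' Created by [matchConfig()]; see that constructor for the meaning and
#' defaults of every field.
#'
#' @slot ignore_metabolites Character vector of currency-species labels to
#'   drop from both reaction sides before comparing (default electrons,
#'   protons, water).
#' @slot h_tolerant_formula Disregard H counts in formula comparison?
#' @slot override_pairs data.frame of forced metabolite matches (columns
#'   \code{a}, \code{b}: descriptors \code{"namespace:id"} or
#'   \code{"snapshot:local_id"}).
#' @slot generic_specific_guard Forbid generic/specific matches?
#' @slot name_requires_formula Name matches require equal formulas on both
#'   records?
#' @aliases MatchConfig
#' @export
setClass("MatchConfig",
  representation(ignore_metabolites = "character",
                 h_tolerant_formula = "logical",
                 override_pairs = "data.frame",
                 generic_specific_guard = "logical",
                 name_requires_formula = "logical")
)

# ---- MatchPartition ---------------------------------------------------------

#' MatchPartition: equivalence classes over entities of several snapshots
#'
#' The result of transitive closure over pairwise entity matches. Each
#' compared entity belongs to exactly one class; the class id is the
#' lexicographically smallest member key so outputs are deterministic.
#'
#' @slot entity_class One of \code{"gene"}, \code{"ec"}, \code{"metabolite"},
#'   \code{"reaction"}.
#' @slot membership data.frame with columns \code{key}
#'   (\code{snapshot::local_id}), \code{snapshot}, \code{local_id},
#'   \code{class_id}, and \code{excluded_reason} (\code{NA} for countable
#'   members; e.g. \code{"degenerate"} for reactions whose relaxed signature
#'   collapses).
#' @slot evidence data.frame with columns \code{from}, \code{to},
#'   \code{route}: the pairwise match evidence that produced the closure.
#' @slot excluded data.frame with columns \code{key}, \code{reason}: entities
#'   left out of the comparison entirely (no shared identifier, partial EC).
#' @aliases MatchPartition
#' @export
setClass("MatchPartition",
  representation(entity_class = "character", membership = "data.frame",
                 evidence = "data.frame", excluded = "data.frame")
)

setValidity("MatchPartition", function(object) {
  msgs <- character(0)
  if (!object@entity_class %in% c("gene", "ec", "metabolite", "reaction"))
    msgs <- c(msgs, "entity_class must be gene, ec, metabolite or reaction")
  mb <- object@membership
  if (nrow(mb) > 0) {
    if (anyDuplicated(mb$key))
      msgs <- c(msgs, "membership keys are not unique (classes must be disjoint)")
    reps <- tapply(mb$key, mb$class_id, min)
    bad <- names(reps)[names(reps) != unname(reps)]
    if (length(bad))
      msgs <- c(msgs, sprintf(
        "class_id is not the smallest member key for: %s", joinSet(bad)))
  }
  if (length(msgs)) msgs else TRUE
})

# ---- ComparisonResult -------------------------------------------------------

#' ComparisonResult: agreement statistics for one entity class
#'
#' Produced by [consensus()]. Counts are over identity classes; percentages
#' are round-half-up whole percentages of the union.
#'
#' @slot snapshots Snapshot names compared.
#' @slot union_size Number of distinct classes in the union.
#' @slot occurrence_histogram Named integer vector: for k = 1..N, the number
#'   of classes present in exactly k snapshots.
#' @slot consensus_count,consensus_pct Classes present in all N snapshots.
#' @slot majority_count,majority_pct Classes present in at least
#'   \code{majority_threshold} snapshots.
#' @slot majority_threshold Majority threshold used (default 3).
#' @slot unique_per_snapshot Named integer: classes found in that snapshot
#'   only.
#' @slot excluded Named integer: non-comparable entities per reason.
#' @aliases ComparisonResult
#' @export
setClass("ComparisonResult",
  representation(snapshots = "character", union_size = "integer",
                 occurrence_histogram = "integer",
                 consensus_count = "integer", consensus_pct = "integer",
                 majority_count = "integer", majority_pct = "integer",
                 majority_threshold = "integer",
                 unique_per_snapshot = "integer", excluded = "integer")
)

setValidity("ComparisonResult", function(object) {
  msgs <- character(0)
  n <- length(object@snapshots)
  h <- object@occurrence_histogram
  if (length(h) != n) msgs <- c(msgs, "histogram must have one bin per snapshot count")
  if (sum(h) != object@union_size)
    msgs <- c(msgs, "histogram bins must sum to union_size")
  if (length(h) == n && n > 0 && object@consensus_count != h[[n]])
    msgs <- c(msgs, "consensus_count must equal histogram[N]")
  if (object@majority_count !=
      sum(h[seq_along(h) >= object@majority_threshold]))
    msgs <- c(msgs, "majority_count must equal sum of histogram[k >= threshold]")
  if (length(h) >= 1 && sum(object@unique_per_snapshot) != h[[1]])
    msgs <- c(msgs, "unique counts must sum to histogram[1]")
  if (length(msgs)) msgs else TRUE
})

# ---- Synthetic-data classes -------------------------------------------------

#' GroundTruth: reference network behind synthetic snapshots
#'
#' A fully identified metabolic network (every metabolite carries a primary
#' compound identifier, every reaction its genes, EC number and pathway) from
#' which perturbed [DatabaseSnapshot] objects are derived. Linear chains of
#' reactions eligible for lumping into a net reaction are annotated as
#' routes.
#'
#' @slot snapshot A [DatabaseSnapshot] holding the reference content (name
#'   \code{"truth"}).
#' @slot routes data.frame with columns \code{route_id} and list column
#'   \code{reaction_ids}: maximal chains eligible for lumping.
#' @slot update_tables [UpdateTables] mapping synthetic old identifiers to
#'   the truth identifiers (used by the obsolete-identifier perturbation).
#' @slot alt_pairs data.frame \code{from}, \code{to}: cosubstrate swaps
#'   available to the alternative-substrate perturbation.
#' @slot truth_hash Fingerprint used to refuse mixing ledgers from different
#'   truths.
#' @slot seed Seed the truth was generated under.
#' @aliases GroundTruth
#' @export
setClass("GroundTruth",
  representation(snapshot = "DatabaseSnapshot", routes = "data.frame",
                 update_tables = "UpdateTables", alt_pairs = "data.frame",
                 truth_hash = "character", seed = "integer")
)

#' PerturbationProfile: how a synthetic snapshot diverges from the truth
#'
#' Each probability acts independently per eligible entity. Created by
#' [perturbationProfile()]; all probabilities default to 0 so the default
#' profile reproduces the truth exactly (up to local-id relabeling).
#'
#' @slot p_cov Reaction inclusion probability (coverage).
#' @slot p_id_drop Named numeric: per-namespace identifier dropout
#'   probability.
#' @slot p_name_variant Probability of replacing the primary name by a
#'   recoverable case/punctuation variant, or (half of the time variants are
#'   drawn) by an unrecoverable hard synonym.
#' @slot p_proton_shift Probability of shifting the formula by one H and
#'   suffixing the primary name with a charge tag.
#' @slot p_lump Probability that an eligible route is emitted as its single
#'   net reaction.
#' @slot p_alt_substrate Probability of emitting an additional
#'   cosubstrate-swapped copy of a reaction.
#' @slot p_generic Probability of replacing a specific participant by its
#'   generic class.
#' @slot p_obsolete_inject Probability of replacing a primary compound id by
#'   a superseded synthetic id (repairable via the truth's update tables).
#' @slot p_flip_direction Probability of swapping reaction sides.
#' @slot p_balance_h2o_hplus Probability of adding/removing a proton or
#'   water on one side.
#' @slot p_drop_pathway Probability of removing a reaction's pathway
#'   assignment.
#' @slot seed Integer seed; same profile + seed gives a byte-identical
#'   snapshot.
#' @aliases PerturbationProfile
#' @export
setClass("PerturbationProfile",
  representation(p_cov = "numeric", p_id_drop = "numeric",
                 p_name_variant = "numeric", p_proton_shift = "numeric",
                 p_lump = "numeric", p_alt_substrate = "numeric",
                 p_generic = "numeric", p_obsolete_inject = "numeric",
                 p_flip_direction = "numeric",
                 p_balance_h2o_hplus = "numeric", p_drop_pathway = "numeric",
                 seed = "integer")
)

setValidity("PerturbationProfile", function(object) {
  pr <- c(object@p_cov, object@p_id_drop, object@p_name_variant,
          object@p_proton_shift, object@p_lump, object@p_alt_substrate,
          object@p_generic, object@p_obsolete_inject,
          object@p_flip_direction, object@p_balance_h2o_hplus,
          object@p_drop_pathway)
  if (any(pr < 0 | pr > 1)) "all probabilities must lie in [0, 1]" else TRUE
})

#' TruthLedger: per-snapshot bookkeeping of synthetic provenance
#'
#' Maps every emitted entity of a derived snapshot back to its ground-truth
#' identity (or lump-group id) together with the perturbations applied to
#' it, enabling oracle computation of the true overlap independent of the
#' matcher.
#'
#' @slot snapshot Name of the derived snapshot.
#' @slot truth_hash Fingerprint of the generating [GroundTruth].
#' @slot entries data.frame with columns \code{entity_class},
#'   \code{local_id}, \code{truth_id}, \code{tags} (comma-joined
#'   perturbation labels).
#' @aliases TruthLedger
#' @export
setClass("TruthLedger",
  representation(snapshot = "character", truth_hash = "character",
                 entries = "data.frame")
)

setValidity("TruthLedger", function(object) {
  e <- object@entries
  if (anyDuplicated(paste(e$entity_class, e$local_id)))
    "every emitted entity must appear exactly once" else TRUE
})
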