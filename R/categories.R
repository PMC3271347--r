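#' @include combinations.R
NULL

#' Assign pathway categories from a mapping table
#'
#' Sets the \code{category} column of the snapshot's pathway table from a
#' mapping (pathway local_id or pathway name -> category label). Pathways
#' the mapping does not cover fall back to \code{"miscellaneous"} with a
#' warning. Reactions — and through them genes and EC numbers — inherit the
#' categories of every pathway they belong to, so an entity may carry
#' several categories; reactions assigned to no pathway carry none.
#'
#' @param snap A [DatabaseSnapshot].
#' @param mapping data.frame with columns \code{pathway} (local_id or name)
#'   and \code{category} (values from [categoryLabels()]), or a path to a
#'   two-column TSV of the same shape.
#' @return The snapshot with pathway categories set.
#' @export
assignCategories <- function(snap, mapping) {
  if (is.character(mapping) && length(mapping) == 1)
    mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE,
                                 colClasses = "character", quote = "")
  stopifnot(all(c("pathway", "category") %in% names(mapping)))
  bad <- setdiff(mapping$category, categoryLabels())
  if (length(bad))
    stop("unknown category label(s): ", joinSet(bad), call. = FALSE)
  p <- pathways(snap)
  if (nrow(p) == 0) return(snap)
  hit <- match(p$local_id, mapping$pathway)
  hit_name <- match(p$name, mapping$pathway)
  hit[is.na(hit)] <- hit_name[is.na(hit)]
  p$category <- ifelse(is.na(hit), NA_character_, mapping$category[hit])
  if (anyNA(p$category)) {
    warning("pathway(s) not covered by the category mapping, assigned ",
            "'miscellaneous': ", joinSet(p$local_id[is.na(p$category)]),
            call. = FALSE)
    p$category[is.na(p$category)] <- "miscellaneous"
  }
  out <- new("DatabaseSnapshot", name = snapshotName(snap),
             genes = genes(snap), metabolites = metabolites(snap),
             reactions = reactions(snap), pathways = p)
  validObject(out)
  out
}

# categories of each reaction (union over its pathways); list per reaction
reactionCategories <- function(snap) {
  p <- pathways(snap)
  cat_of <- stats::setNames(p$category, p$local_id)
  lapply(reactions(snap)$pathways, function(pw) {
    cats <- cat_of[pw]
    sort(unique(cats[!is.na(cats)]))
  })
}

#' Is a reaction a transport reaction?
#'
#' A reaction is transport when its participants are not all localized in
#' one compartment. Metabolites without a compartment annotation share a
#' single "unspecified" pseudo-compartment, so snapshots with incomplete
#' compartment annotation are not spuriously full of transport reactions.
#' The test is symmetric in the two sides.
#'
#' @param reaction One-row slice of \code{reactions(snap)}.
#' @param snap The [DatabaseSnapshot] the reaction belongs to.
#' @return \code{TRUE} iff more than one distinct compartment occurs.
#' @export
isTransport <- function(reaction, snap) {
  m <- metabolites(snap)
  comp_of <- stats::setNames(m$compartment, m$local_id)
  ids <- c(names(reaction$side_a[[1]]), names(reaction$side_b[[1]]))
  comps <- comp_of[ids]
  comps[is.na(comps)] <- "<unspecified>"
  length(unique(comps)) > 1
}

#' Is a reaction macromolecular?
#'
#' @param reaction One-row slice of \code{reactions(snap)}.
#' @param snap The [DatabaseSnapshot] the reaction belongs to.
#' @return \code{TRUE} iff at least one participant is flagged as a protein
#'   (\code{is_protein}).
#' @export
isMacromolecular <- function(reaction, snap) {
  m <- metabolites(snap)
  prot <- stats::setNames(m$is_protein, m$local_id)
  ids <- c(names(reaction$side_a[[1]]), names(reaction$side_b[[1]]))
  any(prot[ids], na.rm = TRUE)
}

# restrict a snapshot to a set of reaction local_ids, pruning the other
# tables to what those reactions reference (instances of kept generic
# classes are retained so class/instance structure stays intact)
subsetSnapshot <- function(snap, reaction_ids) {
  r <- reactions(snap)
  r <- r[r$local_id %in% reaction_ids, , drop = FALSE]
  rownames(r) <- NULL
  m <- metabolites(snap)
  keep_m <- unique(unlist(lapply(c(r$side_a, r$side_b), names)))
  repeat {
    inst <- unique(unlist(m$instance_ids[m$local_id %in% keep_m]))
    grown <- union(keep_m, inst)
    if (length(grown) == length(keep_m)) break
    keep_m <- grown
  }
  m <- m[m$local_id %in% keep_m, , drop = FALSE]
  rownames(m) <- NULL
  g <- genes(snap)
  g <- g[g$local_id %in% unique(unlist(r$genes)), , drop = FALSE]
  rownames(g) <- NULL
  p <- pathways(snap)
  p <- p[p$local_id %in% unique(unlist(r$pathways)), , drop = FALSE]
  rownames(p) <- NULL
  out <- new("DatabaseSnapshot", name = snapshotName(snap), genes = g,
             metabolites = m, reactions = r, pathways = p)
  validObject(out)
  out
}

#' Restrict a snapshot to core metabolic processes
#'
#' Retains the reactions carrying at least one of the six core categories
#' (see [coreCategories()]); reactions in no pathway have no category and
#' drop out. Transport reactions and — where configured — macromolecular
#' reactions (any participant flagged protein) are removed as peripheral to
#' metabolism proper. The operation is idempotent and its output is a valid
#' snapshot.
#'
#' @param snap A [DatabaseSnapshot] with categories assigned.
#' @param drop_macromolecular Remove macromolecular reactions from this
#'   snapshot? Databases that intertwine proteins with small molecules
#'   warrant \code{TRUE}; purely small-molecule snapshots can keep the
#'   default \code{FALSE}.
#' @param drop_transport Remove transport reactions (default \code{TRUE}).
#' @param core Category labels defining the core (default
#'   [coreCategories()]).
#' @return The restricted [DatabaseSnapshot].
#' @export
coreSubset <- function(snap, drop_macromolecular = FALSE,
                       drop_transport = TRUE, core = coreCategories()) {
  r <- reactions(snap)
  if (nrow(r) == 0) return(snap)
  cats <- reactionCategories(snap)
  keep <- vapply(cats, function(cc) any(cc %in% core), logical(1))
  if (drop_transport)
    keep <- keep & !vapply(seq_len(nrow(r)), function(i)
      isTransport(r[i, ], snap), logical(1))
  if (drop_macromolecular)
    keep <- keep & !vapply(seq_len(nrow(r)), function(i)
      isMacromolecular(r[i, ], snap), logical(1))
  subsetSnapshot(snap, r$local_id[keep])
}
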