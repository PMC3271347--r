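#' @include AllGenerics.R
NULL

#' Construct a DatabaseSnapshot
#'
#' Normalizes user-supplied tables into the canonical column layout,
#' deduplicates synonym lists (after [normalizeName()]; the first spelling of
#' each normalized form is kept) and validates referential integrity.
#'
#' @param name Snapshot name (the database label used in all reports).
#' @param genes data.frame with \code{local_id} and optional \code{gene_id}.
#' @param metabolites data.frame; missing optional columns are filled with
#'   \code{NA}/empty defaults. \code{names} may be a character column (single
#'   name) or a list column.
#' @param reactions data.frame; \code{side_a}/\code{side_b} must be list
#'   columns of named numeric vectors (metabolite local_id -> coefficient).
#' @param pathways data.frame with \code{local_id}, \code{name}, optional
#'   \code{category}.
#' @return A validated [DatabaseSnapshot].
#' @examples
#' s <- databaseSnapshot("demo",
#'   genes = data.frame(local_id = "g1", gene_id = "1737"),
#'   metabolites = data.frame(local_id = c("m1", "m2"),
#'                            names = c("pyruvate", "water"),
#'                            kegg_compound = c("C00022", "C00001")),
#'   reactions = data.frame(local_id = "r1",
#'     side_a = I(list(c(m1 = 1))), side_b = I(list(c(m2 = 1)))))
#' snapshotName(s)
#' @export
databaseSnapshot <- function(name, genes = NULL, metabolites = NULL,
                             reactions = NULL, pathways = NULL) {
  g <- normalizeGeneTable(genes)
  m <- normalizeMetaboliteTable(metabolites)
  r <- normalizeReactionTable(reactions)
  p <- normalizePathwayTable(pathways)
  new("DatabaseSnapshot", name = as.character(name), genes = g,
      metabolites = m, reactions = r, pathways = p)
}

normalizeGeneTable <- function(genes) {
  if (is.null(genes) || nrow(genes) == 0) return(emptyGenes())
  data.frame(local_id = as.character(genes$local_id),
             gene_id = if ("gene_id" %in% names(genes))
               as.character(genes$gene_id) else NA_character_,
             stringsAsFactors = FALSE)
}

normalizeMetaboliteTable <- function(mets) {
  if (is.null(mets) || nrow(mets) == 0) return(emptyMetabolites())
  n <- nrow(mets)
  chrcol <- function(col) {
    if (col %in% names(mets)) as.character(mets[[col]]) else
      rep(NA_character_, n)
  }
  lglcol <- function(col) {
    if (col %in% names(mets)) {
      v <- as.logical(mets[[col]])
      v[is.na(v)] <- FALSE
      v
    } else rep(FALSE, n)
  }
  nm <- if (is.list(mets$names)) mets$names else as.list(as.character(mets$names))
  nm <- lapply(nm, dedupeNames)
  inst <- if ("instance_ids" %in% names(mets)) {
    if (is.list(mets$instance_ids)) mets$instance_ids
    else lapply(as.character(mets$instance_ids), splitList)
  } else rep(list(character(0)), n)
  inst <- lapply(inst, function(x) as.character(x %||% character(0)))
  df <- data.frame(
    local_id = as.character(mets$local_id),
    formula = chrcol("formula"),
    charge = if ("charge" %in% names(mets)) as.integer(mets$charge) else
      rep(NA_integer_, n),
    compartment = chrcol("compartment"),
    kegg_compound = chrcol("kegg_compound"),
    kegg_glycan = chrcol("kegg_glycan"),
    chebi = chrcol("chebi"),
    pubchem_compound = chrcol("pubchem_compound"),
    cas = chrcol("cas"),
    is_generic = lglcol("is_generic"),
    is_protein = lglcol("is_protein"),
    stringsAsFactors = FALSE
  )
  df$names <- nm
  df$instance_ids <- inst
  df
}

# keep the first spelling of each normalized synonym
dedupeNames <- function(x) {
  x <- as.character(x)
  x <- x[!is.na(x) & nzchar(x)]
  x[!duplicated(normalizeName(x))]
}

normalizeReactionTable <- function(rxns) {
  if (is.null(rxns) || nrow(rxns) == 0) return(emptyReactions())
  n <- nrow(rxns)
  lstcol <- function(col) {
    if (col %in% names(rxns)) lapply(rxns[[col]], function(x)
      as.character(x %||% character(0)))
    else rep(list(character(0)), n)
  }
  side <- function(col) lapply(rxns[[col]], function(s) {
    s <- unlist(s)
    stopifnot(!is.null(names(s)))
    v <- as.numeric(s)
    names(v) <- names(s)
    v[order(names(v))]
  })
  df <- data.frame(
    local_id = as.character(rxns$local_id),
    reversible = if ("reversible" %in% names(rxns))
      as.logical(rxns$reversible) else rep(NA, n),
    is_set_reaction = if ("is_set_reaction" %in% names(rxns)) {
      v <- as.logical(rxns$is_set_reaction); v[is.na(v)] <- FALSE; v
    } else rep(FALSE, n),
    expansion_flagged = if ("expansion_flagged" %in% names(rxns)) {
      v <- as.logical(rxns$expansion_flagged); v[is.na(v)] <- FALSE; v
    } else rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  df$side_a <- side("side_a")
  df$side_b <- side("side_b")
  df$genes <- lstcol("genes")
  df$ecs <- lstcol("ecs")
  df$pathways <- lstcol("pathways")
  df
}

normalizePathwayTable <- function(pws) {
  if (is.null(pws) || nrow(pws) == 0) return(emptyPathways())
  data.frame(local_id = as.character(pws$local_id),
             name = if ("name" %in% names(pws)) as.character(pws$name) else
               as.character(pws$local_id),
             category = if ("category" %in% names(pws))
               as.character(pws$category) else NA_character_,
             stringsAsFactors = FALSE)
}

# ---- accessors --------------------------------------------------------------

#' @rdname accessors
setMethod("snapshotName", "DatabaseSnapshot", function(x) x@name)

#' @rdname accessors
setMethod("genes", "DatabaseSnapshot", function(x) x@genes)

#' @rdname accessors
setMethod("metabolites", "DatabaseSnapshot", function(x) x@metabolites)

#' @rdname accessors
setMethod("reactions", "DatabaseSnapshot", function(x) x@reactions)

#' @rdname accessors
setMethod("pathways", "DatabaseSnapshot", function(x) x@pathways)

#' @rdname accessors
setMethod("membership", "MatchPartition", function(x) x@membership)

#' @rdname accessors
setMethod("evidence", "MatchPartition", function(x) x@evidence)

#' @rdname accessors
setMethod("excludedEntities", "MatchPartition", function(x) x@excluded)

#' @rdname accessors
setMethod("truthEntries", "TruthLedger", function(x) x@entries)

#' @rdname accessors
setMethod("truthSnapshot", "GroundTruth", function(x) x@snapshot)

#' @rdname comparison-accessors
setMethod("unionSize", "ComparisonResult", function(x) x@union_size)

#' @rdname comparison-accessors
setMethod("consensusPct", "ComparisonResult", function(x) x@consensus_pct)

#' @rdname comparison-accessors
setMethod("majorityPct", "ComparisonResult", function(x) x@majority_pct)

#' @rdname comparison-accessors
setMethod("occurrenceHistogram", "ComparisonResult",
          function(x) x@occurrence_histogram)

#' @rdname comparison-accessors
setMethod("uniqueCounts", "ComparisonResult",
          function(x) x@unique_per_snapshot)

# ---- show methods -----------------------------------------------------------

setMethod("show", "DatabaseSnapshot", function(object) {
  cat(sprintf("DatabaseSnapshot '%s'\n", object@name))
  cat(sprintf("  genes: %d  metabolites: %d  reactions: %d  pathways: %d\n",
              nrow(object@genes), nrow(object@metabolites),
              nrow(object@reactions), nrow(object@pathways)))
})

setMethod("show", "MatchPartition", function(object) {
  mb <- object@membership
  cat(sprintf("MatchPartition over %ss\n", object@entity_class))
  cat(sprintf("  %d entities in %d classes (%d excluded, %d non-countable)\n",
              nrow(mb), length(unique(mb$class_id)), nrow(object@excluded),
              sum(!is.na(mb$excluded_reason))))
})

setMethod("show", "ComparisonResult", function(object) {
  n <- length(object@snapshots)
  cat(sprintf("ComparisonResult over %d snapshots (%s)\n", n,
              paste(object@snapshots, collapse = ", ")))
  cat(sprintf("  union: %d\n", object@union_size))
  cat(sprintf("  consensus: %d (%d%%)\n", object@consensus_count,
              object@consensus_pct))
  cat(sprintf("  majority (>= %d of %d): %d (%d%%)\n",
              object@majority_threshold, n, object@majority_count,
              object@majority_pct))
  up <- object@unique_per_snapshot
  cat(sprintf("  unique: %s (total %d)\n",
              paste(sprintf("%s=%d", names(up), up), collapse = ", "),
              sum(up)))
  if (length(object@excluded) && sum(object@excluded) > 0)
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%s=%d", names(object@excluded),
                              object@excluded), collapse = ", ")))
})

setMethod("show", "GroundTruth", function(object) {
  s <- object@snapshot
  cat(sprintf(
    "GroundTruth (seed %d): %d metabolites, %d reactions, %d pathways, %d lumpable routes\n",
    object@seed, nrow(s@metabolites), nrow(s@reactions), nrow(s@pathways),
    nrow(object@routes)))
})

setMethod("show", "TruthLedger", function(object) {
  cat(sprintf("TruthLedger for snapshot '%s': %d entries\n",
              object@snapshot, nrow(object@entries)))
})

setMethod("show", "PerturbationProfile", function(object) {
  cat("PerturbationProfile\n")
  cat(sprintf("  p_cov=%.2f p_lump=%.2f p_generic=%.2f p_alt=%.2f seed=%d\n",
              object@p_cov, object@p_lump, object@p_generic,
              object@p_alt_substrate, object@seed))
  drops <- object@p_id_drop[object@p_id_drop > 0]
  if (length(drops))
    cat(sprintf("  id dropout: %s\n",
                paste(sprintf("%s=%.2f", names(drops), drops),
                      collapse = ", ")))
})
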