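#' @include io.R
NULL

#' Apply identifier transfer/obsolescence tables to a snapshot
#'
#' Every identifier (gene, the five metabolite namespaces, EC numbers) found
#' in the \code{transferred} map of \code{tables} is replaced by its current
#' form; identifiers listed as \code{obsolete} are removed, but the record
#' itself is always retained — an entity that loses an identifier can still
#' match through the remaining routes. Identifiers mentioned in no table
#' pass through unchanged, so the operation is idempotent (transfer maps are
#' pre-flattened).
#'
#' @param snap A [DatabaseSnapshot].
#' @param tables An [UpdateTables] object.
#' @return The updated snapshot, with a summary of replacement/removal
#'   counts per namespace in \code{attr(, "update_summary")}.
#' @examples
#' s <- databaseSnapshot("d", genes = data.frame(local_id = "g",
#'                                               gene_id = "123"))
#' s2 <- applyIdentifierUpdates(s,
#'   updateTables(transferred = list(gene = c("123" = "456"))))
#' genes(s2)$gene_id  # "456"
#' @export
applyIdentifierUpdates <- function(snap, tables) {
  stopifnot(is(snap, "DatabaseSnapshot"), is(tables, "UpdateTables"))
  summary <- list()
  apply_ns <- function(values, ns) {
    tr <- tables@transferred[[ns]] %||% character(0)
    ob <- tables@obsolete[[ns]] %||% character(0)
    hit_tr <- !is.na(values) & values %in% names(tr)
    values[hit_tr] <- unname(tr[values[hit_tr]])
    hit_ob <- !is.na(values) & values %in% ob
    values[hit_ob] <- NA_character_
    summary[[ns]] <<- c(replaced = sum(hit_tr), removed = sum(hit_ob))
    values
  }
  g <- genes(snap)
  g$gene_id <- apply_ns(g$gene_id, "gene")
  m <- metabolites(snap)
  for (ns in metNamespaces()) m[[ns]] <- apply_ns(m[[ns]], ns)
  r <- reactions(snap)
  ec_tr <- tables@transferred[["ec"]] %||% character(0)
  ec_ob <- tables@obsolete[["ec"]] %||% character(0)
  n_rep <- 0L; n_rem <- 0L
  r$ecs <- lapply(r$ecs, function(ecs) {
    hit_tr <- ecs %in% names(ec_tr)
    ecs[hit_tr] <- unname(ec_tr[ecs[hit_tr]])
    hit_ob <- ecs %in% ec_ob
    n_rep <<- n_rep + sum(hit_tr); n_rem <<- n_rem + sum(hit_ob)
    unique(ecs[!hit_ob])
  })
  summary[["ec"]] <- c(replaced = n_rep, removed = n_rem)
  out <- new("DatabaseSnapshot", name = snapshotName(snap), genes = g,
             metabolites = m, reactions = r, pathways = pathways(snap))
  validObject(out)
  attr(out, "update_summary") <- summary
  out
}
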