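#' @include categories.R
NULL

# pathway local_ids in snap whose name (or alias) matches `scope`
resolvePathwayScope <- function(snap, scope, aliases = NULL) {
  p <- pathways(snap)
  wanted <- scope
  if (!is.null(aliases)) {
    al <- aliases[[snapshotName(snap)]]
    if (!is.null(al)) wanted <- c(wanted, al)
  }
  norm <- normalizeName(wanted)
  hit <- p$local_id %in% wanted | normalizeName(p$name) %in% norm
  p$local_id[hit]
}

#' Comparison restricted to a pathway or to pathway categories
#'
#' Re-runs the full multi-level comparison (genes, EC numbers, metabolites,
#' reactions) on the subset of each snapshot that falls inside the scope:
#' either one named pathway (a single-pathway case study such as the TCA
#' cycle; per-snapshot pathway names can differ, supply them via
#' \code{pathway_aliases}) or a set of categories (e.g. the core-metabolism
#' comparison via [coreCategories()]). For a pathway scope the reaction
#' classes of the result also support matching genes and EC numbers within
#' matching reactions via [combinationReactionGeneEC()] on the returned
#' subsets.
#'
#' @param snapshots List of [DatabaseSnapshot] objects.
#' @param pathway Pathway name defining the scope (matched
#'   case/punctuation-insensitively against pathway names and local ids).
#' @param pathway_aliases Named list snapshot -> alternative pathway names,
#'   for databases labeling the pathway differently.
#' @param categories Character vector of category labels defining the scope
#'   (alternative to \code{pathway}).
#' @param drop_macromolecular Character vector of snapshot names whose
#'   macromolecular reactions are removed (category scope only).
#' @param drop_transport Remove transport reactions (category scope only;
#'   default \code{TRUE}).
#' @param cfg A [MatchConfig].
#' @param majority_threshold Majority threshold (default 3).
#' @return As [compareSnapshots()], plus element \code{subsets}: the
#'   restricted snapshots the statistics were computed on.
#' @export
restrictedCompare <- function(snapshots, pathway = NULL,
                              pathway_aliases = NULL, categories = NULL,
                              drop_macromolecular = character(0),
                              drop_transport = TRUE, cfg = matchConfig(),
                              majority_threshold = 3L) {
  if (is.null(pathway) == is.null(categories))
    stop("give exactly one of 'pathway' or 'categories'", call. = FALSE)
  if (!is.null(pathway)) {
    missing_in <- character(0)
    subsets <- lapply(snapshots, function(s) {
      pw <- resolvePathwayScope(s, pathway, pathway_aliases)
      r <- reactions(s)
      keep <- vapply(r$pathways, function(x) any(x %in% pw), logical(1))
      if (!any(keep)) missing_in <<- c(missing_in, snapshotName(s))
      subsetSnapshot(s, r$local_id[keep])
    })
    if (length(missing_in))
      stop("scope '", pathway, "' is empty in snapshot(s): ",
           paste(missing_in, collapse = ", "), call. = FALSE)
  } else {
    bad <- setdiff(categories, categoryLabels())
    if (length(bad))
      stop("unknown category label(s): ", joinSet(bad), call. = FALSE)
    missing_in <- character(0)
    subsets <- lapply(snapshots, function(s) {
      sub <- coreSubset(
        s, drop_macromolecular = snapshotName(s) %in% drop_macromolecular,
        drop_transport = drop_transport, core = categories)
      if (nrow(reactions(sub)) == 0)
        missing_in <<- c(missing_in, snapshotName(s))
      sub
    })
    if (length(missing_in))
      stop("category scope is empty in snapshot(s): ",
           paste(missing_in, collapse = ", "), call. = FALSE)
  }
  out <- compareSnapshots(subsets, cfg = cfg,
                          majority_threshold = majority_threshold)
  out$subsets <- subsets
  out
}
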