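#' @include reactions.R
NULL

#' Resolve gene identity across snapshots
#'
#' Genes are compared on their shared-namespace identifier (Entrez-style
#' digit strings): records with identical \code{gene_id} form one class. No
#' distinction is made between a gene encoding a whole catalyst and one
#' encoding a component of a complex. Records with no \code{gene_id} cannot
#' take part in the comparison and are reported in the partition's excluded
#' table with reason \code{"no_shared_identifier"}.
#'
#' @param snapshots List of [DatabaseSnapshot] objects (identifier updates
#'   already applied).
#' @return A [MatchPartition] over genes.
#' @export
buildGenePartition <- function(snapshots) {
  rows <- lapply(snapshots, function(s) {
    g <- genes(s)
    if (nrow(g) == 0) return(NULL)
    data.frame(key = entityKey(snapshotName(s), g$local_id),
               snapshot = snapshotName(s), local_id = g$local_id,
               gene_id = g$gene_id, stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, rows)
  if (is.null(recs)) return(emptyPartition("gene"))
  has_id <- !is.na(recs$gene_id)
  inc <- recs[has_id, , drop = FALSE]
  class_id <- if (nrow(inc)) stats::ave(inc$key, inc$gene_id, FUN = min)
    else character(0)
  new("MatchPartition", entity_class = "gene",
      membership = data.frame(
        key = inc$key, snapshot = inc$snapshot, local_id = inc$local_id,
        class_id = class_id,
        excluded_reason = rep(NA_character_, nrow(inc)),
        stringsAsFactors = FALSE),
      evidence = evidenceChains(inc$key, class_id, "identical_gene"),
      excluded = data.frame(key = recs$key[!has_id],
                            reason = rep("no_shared_identifier",
                                         sum(!has_id)),
                            stringsAsFactors = FALSE))
}

#' Parse EC number strings
#'
#' @param ec Character vector of dot-joined EC numbers; a trailing
#'   \code{"-"} marks a partial (incompletely specified) number.
#' @return data.frame with integer columns \code{c1..c3}, \code{c4}
#'   (\code{NA} for partial) and logical \code{partial}.
#' @examples
#' parseEC(c("1.1.1.1", "1.1.1.-"))
#' @export
parseEC <- function(ec) {
  stopifnot(all(grepl(ecPattern, ec)))
  parts <- strsplit(ec, ".", fixed = TRUE)
  data.frame(
    c1 = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    c2 = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    c3 = vapply(parts, function(p) as.integer(p[3]), integer(1)),
    c4 = vapply(parts, function(p) suppressWarnings(as.integer(p[4])),
                integer(1)),
    partial = vapply(parts, function(p) p[4] == "-", logical(1)),
    stringsAsFactors = FALSE)
}

#' Resolve EC-number identity across snapshots
#'
#' The EC entities of a snapshot are the distinct EC numbers attached to its
#' reactions. At \code{level = 4} classes group identical complete numbers;
#' at \code{level = 3} they group complete numbers sharing the first three
#' components, giving a coarser comparison of enzymatic function types.
#' Partial EC numbers (such as \code{1.1.1.-}) are semantically ambiguous
#' and are excluded at either level (reason \code{"partial_ec"}).
#'
#' @param snapshots List of [DatabaseSnapshot] objects (EC updates applied).
#' @param level 4 (default) or 3.
#' @return A [MatchPartition] over EC numbers (the \code{local_id} of each
#'   member is the EC string itself).
#' @export
buildECPartition <- function(snapshots, level = 4) {
  stopifnot(level %in% c(3, 4))
  rows <- lapply(snapshots, function(s) {
    ecs <- sort(unique(unlist(reactions(s)$ecs)))
    if (length(ecs) == 0) return(NULL)
    data.frame(key = entityKey(snapshotName(s), ecs),
               snapshot = snapshotName(s), local_id = ecs,
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, rows)
  if (is.null(recs)) return(emptyPartition("ec"))
  info <- parseEC(recs$local_id)
  inc <- recs[!info$partial, , drop = FALSE]
  groups <- if (level == 4) inc$local_id else
    sub("\\.[0-9]+$", "", inc$local_id)
  class_id <- if (nrow(inc)) stats::ave(inc$key, groups, FUN = min)
    else character(0)
  new("MatchPartition", entity_class = "ec",
      membership = data.frame(
        key = inc$key, snapshot = inc$snapshot, local_id = inc$local_id,
        class_id = class_id,
        excluded_reason = rep(NA_character_, nrow(inc)),
        stringsAsFactors = FALSE),
      evidence = evidenceChains(inc$key, class_id, "identical_ec"),
      excluded = data.frame(key = recs$key[info$partial],
                            reason = rep("partial_ec", sum(info$partial)),
                            stringsAsFactors = FALSE))
}
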