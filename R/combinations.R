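#' @include stats.R
NULL

# key -> class_id lookup for a partition
classLookup <- function(partition) {
  mb <- membership(partition)
  stats::setNames(mb$class_id, mb$key)
}

# per snapshot: reaction local_id -> gene classes / EC classes of its links
reactionLinkSets <- function(snap, gene_class, ec_class) {
  r <- reactions(snap)
  snm <- snapshotName(snap)
  gsets <- lapply(r$genes, function(g) {
    cls <- gene_class[entityKey(snm, g)]
    sort(unique(cls[!is.na(cls)]))
  })
  esets <- lapply(r$ecs, function(e) {
    cls <- ec_class[entityKey(snm, e)]
    sort(unique(cls[!is.na(cls)]))     # partial ECs carry no class
  })
  list(genes = stats::setNames(gsets, r$local_id),
       ecs = stats::setNames(esets, r$local_id))
}

allEqualSets <- function(sets) {
  if (length(sets) < 2) return(TRUE)
  all(vapply(sets[-1], function(s) setequal(s, sets[[1]]), logical(1)))
}

#' Two-level agreement: genes and their EC numbers
#'
#' Over the genes in the consensus (gene classes present in every
#' snapshot), compares the sets of complete EC numbers each snapshot
#' connects to the gene (via its reactions). A gene is classified
#' \code{all_ec_agree} when every snapshot links exactly the same non-empty
#' EC set, \code{at_least_one} when the snapshots share at least one EC
#' number, and \code{none} otherwise.
#'
#' @param snapshots List of [DatabaseSnapshot] objects.
#' @param gene_partition Result of [buildGenePartition()] on the same
#'   snapshots.
#' @param ec_partition Result of [buildECPartition()] (level 4).
#' @return List with \code{n_consensus_genes}, per-bucket counts, and
#'   \code{pct_all_ec_agree} / \code{pct_at_least_one} (round-half-up
#'   percentages of the consensus genes).
#' @export
combinationGeneEC <- function(snapshots, gene_partition, ec_partition) {
  nms <- vapply(snapshots, snapshotName, character(1))
  gene_class <- classLookup(gene_partition)
  ec_class <- classLookup(ec_partition)
  sets <- entitySets(gene_partition)
  for (nm in setdiff(nms, names(sets))) sets[[nm]] <- character(0)
  occ <- occurrenceCounts(sets[nms])
  consensus_genes <- names(occ)[occ == length(nms)]
  # gene class -> EC classes, per snapshot
  per_snap <- lapply(snapshots, function(s) {
    snm <- snapshotName(s)
    r <- reactions(s)
    links <- reactionLinkSets(s, gene_class, ec_class)
    out <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(r))) {
      for (gcls in links$genes[[i]]) {
        prev <- get0(gcls, envir = out, ifnotfound = character(0))
        assign(gcls, union(prev, links$ecs[[i]]), envir = out)
      }
    }
    out
  })
  names(per_snap) <- nms
  buckets <- c(all_ec_agree = 0L, at_least_one = 0L, none = 0L)
  for (gcls in consensus_genes) {
    ecsets <- lapply(per_snap, function(env)
      get0(gcls, envir = env, ifnotfound = character(0)))
    if (allEqualSets(ecsets) && length(ecsets[[1]]) > 0) {
      buckets["all_ec_agree"] <- buckets["all_ec_agree"] + 1L
      buckets["at_least_one"] <- buckets["at_least_one"] + 1L
    } else if (length(Reduce(intersect, ecsets)) > 0) {
      buckets["at_least_one"] <- buckets["at_least_one"] + 1L
    } else {
      buckets["none"] <- buckets["none"] + 1L
    }
  }
  n <- length(consensus_genes)
  list(n_consensus_genes = n,
       all_ec_agree = unname(buckets["all_ec_agree"]),
       at_least_one = unname(buckets["at_least_one"]),
       none = unname(buckets["none"]),
       pct_all_ec_agree = if (n > 0) percentRound(buckets["all_ec_agree"], n)
         else NA_integer_,
       pct_at_least_one = if (n > 0) percentRound(buckets["at_least_one"], n)
         else NA_integer_)
}

#' Three-level agreement: reactions, genes and EC numbers
#'
#' Over the consensus reaction classes, compares per snapshot the gene set
#' and the complete-EC set attached to the class (the union over that
#' snapshot's member reactions of the class). Buckets: full three-level
#' agreement (gene sets and EC sets each identical and non-empty across all
#' snapshots), agreement on the EC numbers only, on the genes only, classes
#' with no EC number in common, and classes with no gene in common.
#' Additionally, a class whose gene disagreement consists of some snapshots
#' adding genes on top of a shared core that at least one snapshot reports
#' exactly is tagged \code{additional_genes} — the typical cause of missing
#' full agreement.
#'
#' @param snapshots List of [DatabaseSnapshot] objects.
#' @param partitions List with components \code{gene}, \code{ec},
#'   \code{reaction} (as produced by [compareSnapshots()]).
#' @return List of counts: \code{n_consensus_reactions},
#'   \code{full_agreement}, \code{ec_only}, \code{gene_only},
#'   \code{no_common_ec}, \code{no_common_gene}, \code{additional_genes}.
#' @export
combinationReactionGeneEC <- function(snapshots, partitions) {
  nms <- vapply(snapshots, snapshotName, character(1))
  gene_class <- classLookup(partitions$gene)
  ec_class <- classLookup(partitions$ec)
  rmb <- membership(partitions$reaction)
  rmb <- rmb[is.na(rmb$excluded_reason), , drop = FALSE]
  occ_by_class <- tapply(rmb$snapshot, rmb$class_id,
                         function(s) length(unique(s)))
  consensus_classes <- names(occ_by_class)[occ_by_class == length(nms)]
  links <- lapply(snapshots, function(s)
    reactionLinkSets(s, gene_class, ec_class))
  names(links) <- nms
  counts <- c(full_agreement = 0L, ec_only = 0L, gene_only = 0L,
              no_common_ec = 0L, no_common_gene = 0L,
              additional_genes = 0L)
  for (cls in consensus_classes) {
    members <- rmb[rmb$class_id == cls, , drop = FALSE]
    gsets <- lapply(nms, function(nm) {
      ids <- members$local_id[members$snapshot == nm]
      sort(unique(unlist(links[[nm]]$genes[ids])))
    })
    esets <- lapply(nms, function(nm) {
      ids <- members$local_id[members$snapshot == nm]
      sort(unique(unlist(links[[nm]]$ecs[ids])))
    })
    g_full <- allEqualSets(gsets) && length(gsets[[1]]) > 0
    e_full <- allEqualSets(esets) && length(esets[[1]]) > 0
    g_core <- Reduce(intersect, gsets)
    e_core <- Reduce(intersect, esets)
    if (g_full && e_full) counts["full_agreement"] <-
        counts["full_agreement"] + 1L
    else if (e_full) counts["ec_only"] <- counts["ec_only"] + 1L
    else if (g_full) counts["gene_only"] <- counts["gene_only"] + 1L
    if (length(e_core) == 0) counts["no_common_ec"] <-
        counts["no_common_ec"] + 1L
    if (length(g_core) == 0) counts["no_common_gene"] <-
        counts["no_common_gene"] + 1L
    if (!g_full && length(g_core) > 0 &&
        any(vapply(gsets, function(s) setequal(s, g_core), logical(1))))
      counts["additional_genes"] <- counts["additional_genes"] + 1L
  }
  c(list(n_consensus_reactions = length(consensus_classes)),
    as.list(counts))
}
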