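#' @include matching.R
NULL

# class ids of metabolite classes containing any ignore-set species
ignoreClassIds <- function(met_partition, snapshots, cfg) {
  desc <- resolveIgnoreDescriptors(cfg)
  if (length(desc$kegg) + length(desc$names) == 0) return(character(0))
  hits <- character(0)
  for (s in snapshots) {
    m <- metabolites(s)
    if (nrow(m) == 0) next
    hit <- m$kegg_compound %in% desc$kegg
    if (length(desc$names)) {
      nn <- lapply(m$names, normalizeName)
      hit <- hit | vapply(nn, function(x) any(x %in% desc$names), logical(1))
    }
    hits <- c(hits, entityKey(snapshotName(s), m$local_id[hit]))
  }
  mb <- membership(met_partition)
  unique(mb$class_id[mb$key %in% hits])
}

#' Canonical identity signature of a reaction
#'
#' Each side of the reaction is mapped to the set of metabolite identity
#' classes of its participants (so any two metabolites the partition deems
#' the same compound render identically), members of the configured ignore
#' set are removed, and the two side sets are serialized sorted within and
#' across sides. Direction, compartments and stoichiometric coefficients do
#' not enter the signature: a reaction and its reverse, or the same reaction
#' placed in different compartments, share one signature. A reaction whose
#' two sides become identical sets (including both empty) after removal has
#' no comparable content left and is flagged degenerate.
#'
#' @param reaction One-row slice of \code{reactions(snapshot)}.
#' @param snapshot_name Name of the snapshot the reaction belongs to.
#' @param met_partition [MatchPartition] over metabolites covering this
#'   snapshot.
#' @param cfg A [MatchConfig]; only the ignore set is consulted here. For
#'   efficiency callers may pass the resolved ignore class ids via
#'   \code{ignore_classes} instead.
#' @param ignore_classes Precomputed result of the ignore-set resolution
#'   (internal use).
#' @return Character signature, with attribute \code{degenerate}.
#' @export
reactionSignature <- function(reaction, snapshot_name, met_partition,
                              cfg = matchConfig(), ignore_classes = NULL) {
  mb <- membership(met_partition)
  class_of <- stats::setNames(mb$class_id, mb$key)
  if (is.null(ignore_classes))
    ignore_classes <- attr(met_partition, "ignore_classes") %||% character(0)
  sideClasses <- function(side) {
    keys <- entityKey(snapshot_name, names(side))
    cls <- unname(class_of[keys])
    if (anyNA(cls))
      stop("reaction ", reaction$local_id,
           ": participant(s) missing from metabolite partition", call. = FALSE)
    setdiff(unique(cls), ignore_classes)
  }
  a <- sideClasses(reaction$side_a[[1]])
  b <- sideClasses(reaction$side_b[[1]])
  sides <- sort(c(joinSet(a), joinSet(b)))
  sig <- paste(sides, collapse = " <> ")
  attr(sig, "degenerate") <- setequal(a, b)
  sig
}

#' Group reactions into identity classes by signature
#'
#' Two reactions are the same reaction when all their substrates and
#' products match (modulo the metabolite partition), irrespective of
#' direction, compartment, coefficients and the configured ignore species.
#' Signature equality is an equivalence, so the transitive closure is
#' implicit. The same conversion written in both directions within one
#' snapshot lands in one class and is counted once. Degenerate-signature
#' reactions (e.g. a pure transport of one compound once water and protons
#' are ignored) are excluded from the countable statistics but remain listed
#' in the membership with their reason.
#'
#' @param snapshots List of [DatabaseSnapshot] objects.
#' @param met_partition Metabolite [MatchPartition] built from the same
#'   snapshots with the same \code{cfg}.
#' @param cfg A [MatchConfig].
#' @return A [MatchPartition] over reactions. The signature of every class
#'   is kept in \code{attr(, "signatures")} (named by class id).
#' @export
buildReactionPartition <- function(snapshots, met_partition,
                                   cfg = matchConfig()) {
  ignore_classes <- ignoreClassIds(met_partition, snapshots, cfg)
  rows <- list()
  for (s in snapshots) {
    r <- reactions(s)
    if (nrow(r) == 0) next
    snm <- snapshotName(s)
    sigs <- character(nrow(r)); degen <- logical(nrow(r))
    for (i in seq_len(nrow(r))) {
      sg <- reactionSignature(r[i, ], snm, met_partition, cfg,
                              ignore_classes = ignore_classes)
      sigs[i] <- as.character(sg)
      degen[i] <- attr(sg, "degenerate")
    }
    rows[[snm]] <- data.frame(
      key = entityKey(snm, r$local_id), snapshot = snm,
      local_id = r$local_id, signature = sigs, degenerate = degen,
      stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, rows)
  if (is.null(recs)) return(emptyPartition("reaction"))
  rownames(recs) <- NULL
  class_id <- character(nrow(recs))
  ok <- !recs$degenerate
  class_id[ok] <- stats::ave(recs$key[ok], recs$signature[ok], FUN = min)
  class_id[!ok] <- recs$key[!ok]   # degenerate: singleton class, flagged
  ev <- evidenceChains(recs$key[ok], class_id[ok], "reaction_sides")
  part <- new("MatchPartition", entity_class = "reaction",
      membership = data.frame(
        key = recs$key, snapshot = recs$snapshot, local_id = recs$local_id,
        class_id = class_id,
        excluded_reason = ifelse(recs$degenerate, "degenerate",
                                 NA_character_),
        stringsAsFactors = FALSE),
      evidence = ev,
      excluded = data.frame(key = character(0), reason = character(0),
                            stringsAsFactors = FALSE))
  sig_of <- recs$signature[ok][!duplicated(class_id[ok])]
  names(sig_of) <- class_id[ok][!duplicated(class_id[ok])]
  attr(part, "signatures") <- sig_of
  attr(part, "ignore_classes") <- ignore_classes
  part
}

# spanning-chain evidence rows (smallest member to each other member)
evidenceChains <- function(keys, class_id, route) {
  if (length(keys) == 0)
    return(data.frame(from = character(0), to = character(0),
                      route = character(0), stringsAsFactors = FALSE))
  reps <- stats::ave(keys, class_id, FUN = min)
  keep <- keys != reps
  data.frame(from = reps[keep], to = keys[keep],
             route = rep(route, sum(keep)), stringsAsFactors = FALSE)
}
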