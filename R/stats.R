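#' @include genes_ec.R
NULL

#' Per-snapshot sets of identity classes
#'
#' Converts a [MatchPartition] into the per-snapshot sets \eqn{C_i} of class
#' representatives the agreement statistics are defined on. Non-countable
#' members (degenerate reactions) are dropped; exclusion counts (including
#' entities excluded from the partition entirely) are carried along in
#' \code{attr(, "excluded")}.
#'
#' @param partition A [MatchPartition].
#' @return Named list (one element per snapshot) of sorted class-id vectors.
#' @export
entitySets <- function(partition) {
  mb <- membership(partition)
  ok <- is.na(mb$excluded_reason)
  sets <- lapply(split(mb$class_id[ok], mb$snapshot[ok]),
                 function(x) sort(unique(x)))
  sets <- sets[order(names(sets))]
  reasons <- c(mb$excluded_reason[!ok], excludedEntities(partition)$reason)
  excl <- if (length(reasons)) {
    tb <- table(reasons)
    stats::setNames(as.integer(tb), names(tb))
  } else stats::setNames(integer(0), character(0))
  attr(sets, "excluded") <- excl
  sets
}

occurrenceCounts <- function(sets) {
  all_ids <- unique(unlist(sets))
  if (length(all_ids) == 0) return(integer(0))
  occ <- Reduce(`+`, lapply(sets, function(s) as.integer(all_ids %in% s)))
  stats::setNames(as.integer(occ), all_ids)
}

#' N-way agreement statistics over entity sets
#'
#' Computes the union size, the occurrence histogram (how many classes occur
#' in exactly k snapshots), the consensus — the k = N intersection as a
#' round-half-up percentage of the union — the majority score (classes
#' present in at least \code{majority_threshold} snapshots) and the unique
#' counts per snapshot. The result does not depend on the order of the
#' snapshots.
#'
#' @param sets Named list of class-id vectors, as from [entitySets()].
#' @param majority_threshold Minimum number of snapshots for the majority
#'   score; default 3 (capped at the number of snapshots).
#' @param excluded Optional named integer vector of non-comparable entity
#'   counts to report alongside.
#' @return A [ComparisonResult].
#' @examples
#' sets <- list(A = c("x", "y"), B = c("x"), C = c("x", "z"))
#' consensusPct(consensus(sets))  # 25: 1 of 4 classes in all three
#' @export
consensus <- function(sets, majority_threshold = 3L, excluded = NULL) {
  n <- length(sets)
  stopifnot(n >= 2, !is.null(names(sets)), all(nzchar(names(sets))))
  majority_threshold <- as.integer(min(majority_threshold, n))
  stopifnot(majority_threshold >= 1)
  occ <- occurrenceCounts(sets)
  union_size <- length(occ)
  if (union_size == 0)
    stop("empty union: consensus percentage is undefined", call. = FALSE)
  hist <- stats::setNames(
    vapply(seq_len(n), function(k) sum(occ == k), integer(1)),
    as.character(seq_len(n)))
  uniq <- vapply(sets, function(s) {
    ids <- names(occ)[occ == 1]
    sum(s %in% ids)
  }, integer(1))
  cc <- hist[[n]]
  mc <- sum(hist[seq_len(n) >= majority_threshold])
  if (is.null(excluded))
    excluded <- stats::setNames(integer(0), character(0))
  new("ComparisonResult", snapshots = sort(names(sets)),
      union_size = as.integer(union_size),
      occurrence_histogram = hist,
      consensus_count = as.integer(cc),
      consensus_pct = percentRound(cc, union_size),
      majority_count = as.integer(mc),
      majority_pct = percentRound(mc, union_size),
      majority_threshold = majority_threshold,
      unique_per_snapshot = uniq[order(names(uniq))],
      excluded = excluded)
}

#' Majority score at a chosen threshold
#'
#' Fraction of the union present in at least \code{threshold} of the N
#' snapshots. \code{threshold = N} reproduces the consensus;
#' \code{threshold = 1} is by construction 100\%.
#'
#' @param sets Named list of class-id vectors.
#' @param threshold Integer in \code{1..length(sets)}.
#' @return List with \code{count} and \code{pct} (round-half-up integer).
#' @export
majority <- function(sets, threshold = 3L) {
  n <- length(sets)
  stopifnot(threshold >= 1, threshold <= n)
  occ <- occurrenceCounts(sets)
  if (length(occ) == 0)
    stop("empty union: majority percentage is undefined", call. = FALSE)
  count <- sum(occ >= threshold)
  list(count = as.integer(count), pct = percentRound(count, length(occ)))
}

#' Pairwise overlap matrix on fixed entity sets
#'
#' Entry (i, j) is the two-way consensus
#' \eqn{|C_i \cap C_j| / |C_i \cup C_j| \times 100} on the class sets as
#' given. Note that when matching routes can differ between pairs (they can
#' for metabolites and reactions, where transitive closure through a third
#' snapshot may bridge records), an honest pairwise comparison must rebuild
#' the partition from the two snapshots alone — use [pairwiseCompare()] for
#' that; this function is the pure set formula.
#'
#' @param sets Named list of class-id vectors.
#' @return Symmetric integer matrix of round-half-up percentages, diagonal
#'   100.
#' @export
pairwiseTable <- function(sets) {
  n <- length(sets)
  out <- matrix(100L, n, n, dimnames = list(names(sets), names(sets)))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      u <- length(union(sets[[i]], sets[[j]]))
      v <- if (u == 0) 0L else
        percentRound(length(intersect(sets[[i]], sets[[j]])), u)
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Pairwise comparison with per-pair entity resolution
#'
#' For every pair of snapshots the partition of the requested entity class
#' is rebuilt from those two snapshots alone, so no third database can
#' bridge two records that would not match directly; the two-way consensus
#' is then computed on the resulting sets.
#'
#' @param snapshots List of [DatabaseSnapshot] objects.
#' @param entity_class \code{"gene"}, \code{"ec"}, \code{"metabolite"} or
#'   \code{"reaction"}.
#' @param cfg A [MatchConfig] (used for metabolites and reactions).
#' @param ec_level EC comparison level when \code{entity_class = "ec"}.
#' @return Symmetric integer percentage matrix, diagonal 100.
#' @export
pairwiseCompare <- function(snapshots, entity_class, cfg = matchConfig(),
                            ec_level = 4) {
  nms <- vapply(snapshots, snapshotName, character(1))
  n <- length(snapshots)
  out <- matrix(100L, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      pair <- snapshots[c(i, j)]
      part <- switch(entity_class,
        gene = buildGenePartition(pair),
        ec = buildECPartition(pair, level = ec_level),
        metabolite = buildMetabolitePartition(pair, cfg),
        reaction = buildReactionPartition(
          pair, buildMetabolitePartition(pair, cfg), cfg),
        stop("unknown entity_class: ", entity_class))
      sets <- entitySets(part)
      for (nm in setdiff(nms[c(i, j)], names(sets)))
        sets[[nm]] <- character(0)
      u <- length(union(sets[[nms[i]]], sets[[nms[j]]]))
      v <- if (u == 0) 0L else
        percentRound(length(intersect(sets[[nms[i]]], sets[[nms[j]]])), u)
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Full multi-level comparison of snapshots
#'
#' Builds the gene, EC (complete and 3-level), metabolite and reaction
#' partitions and the corresponding [ComparisonResult]s in one call. The
#' reaction comparison is run with the ignore set from \code{cfg}
#' ("relaxed" when the default electron/proton/water set is active,
#' "strict" when \code{ignore_metabolites} is empty).
#'
#' @param snapshots List of >= 2 [DatabaseSnapshot] objects.
#' @param cfg A [MatchConfig].
#' @param majority_threshold Majority threshold (default 3).
#' @return List with elements \code{partitions} (named list of
#'   [MatchPartition]) and \code{results} (named list of
#'   [ComparisonResult]: gene, ec, ec3, metabolite, reaction).
#' @export
compareSnapshots <- function(snapshots, cfg = matchConfig(),
                             majority_threshold = 3L) {
  stopifnot(length(snapshots) >= 2)
  met_part <- buildMetabolitePartition(snapshots, cfg)
  partitions <- list(
    gene = buildGenePartition(snapshots),
    ec = buildECPartition(snapshots, level = 4),
    ec3 = buildECPartition(snapshots, level = 3),
    metabolite = met_part,
    reaction = buildReactionPartition(snapshots, met_part, cfg))
  nms <- sort(vapply(snapshots, snapshotName, character(1)))
  results <- lapply(partitions, function(p) {
    sets <- entitySets(p)
    if (length(unique(unlist(sets))) == 0) return(NULL)
    excl <- attr(sets, "excluded") %||% stats::setNames(integer(0),
                                                        character(0))
    for (nm in setdiff(nms, names(sets))) sets[[nm]] <- character(0)
    sets <- sets[order(names(sets))]
    consensus(sets, majority_threshold = majority_threshold,
              excluded = excl)
  })
  list(partitions = partitions, results = results)
}
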