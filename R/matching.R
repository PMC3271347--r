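#' @include matchconfig.R
NULL

#' Canonicalize a metabolite name for matching
#'
#' Names are compared case-insensitively with all whitespace and punctuation
#' removed. Strings are first put in Unicode compatibility form (NFKC) so
#' typographic variants of dashes, superscripts and similar collide
#' predictably; no transliteration is performed, so a Greek alpha and the
#' word "alpha" remain distinct.
#'
#' @param raw Character vector of raw names.
#' @return Character vector of canonical names.
#' @examples
#' normalizeName(c("Acetyl-CoA", "acetyl CoA"))  # both "acetylcoa"
#' @export
normalizeName <- function(raw) {
  x <- stringi::stri_trans_nfkc(as.character(raw))
  x <- stringi::stri_replace_all_regex(x, "[\\p{P}\\p{S}\\p{Z}\\s\\p{C}]+", "")
  stringi::stri_trans_tolower(x)
}

# descriptor "namespace:id" or "snapshot:local_id" against one record
matchesDescriptor <- function(rec, snapshot, desc) {
  sep <- regexpr(":", desc, fixed = TRUE)
  if (sep < 0) return(FALSE)
  ns <- substr(desc, 1, sep - 1)
  val <- substr(desc, sep + 1, nchar(desc))
  if (ns %in% metNamespaces())
    return(!is.na(rec[[ns]]) && rec[[ns]] == val)
  if (ns == "name")
    return(normalizeName(val) %in% normalizeName(rec$names[[1]]))
  !is.na(snapshot) && ns == snapshot && rec$local_id == val
}

pairInOverrides <- function(a, b, snap_a, snap_b, cfg) {
  ov <- cfg@override_pairs
  if (nrow(ov) == 0) return(FALSE)
  for (i in seq_len(nrow(ov))) {
    if ((matchesDescriptor(a, snap_a, ov$a[i]) &&
         matchesDescriptor(b, snap_b, ov$b[i])) ||
        (matchesDescriptor(a, snap_a, ov$b[i]) &&
         matchesDescriptor(b, snap_b, ov$a[i])))
      return(TRUE)
  }
  FALSE
}

#' Decide whether two metabolite records refer to the same compound
#'
#' Implements the identifier cascade: (1) hand-curated override pairs force
#' a match; (2) when both records carry a primary compound identifier
#' (KEGG Compound), that comparison is final — equal means match, unequal
#' means no match even if secondary identifiers agree; (3) otherwise any
#' secondary identifier (KEGG Glycan, ChEBI, PubChem Compound, CAS) present
#' on both and equal gives a match; (4) otherwise a shared normalized name
#' gives a match, by default only when both records carry a chemical formula
#' and the formulas agree (H counts disregarded under
#' \code{h_tolerant_formula}). A generic class metabolite never matches a
#' specific one while \code{generic_specific_guard} is on.
#'
#' @param a,b Single metabolite records: one-row slices of
#'   \code{metabolites(snapshot)}.
#' @param cfg A [MatchConfig].
#' @param snap_a,snap_b Snapshot names (needed only to resolve
#'   \code{snapshot:local_id} override descriptors).
#' @param quarantine Normalized names barred from the name route (ambiguous
#'   within a snapshot); used internally by [buildMetabolitePartition()].
#' @return List with elements \code{match} (logical) and \code{route}
#'   (\code{"override"}, \code{"kegg_compound"},
#'   \code{"secondary_id:<namespace>"}, \code{"name+formula"}, or \code{NA}
#'   for no match).
#' @export
metabolitesMatch <- function(a, b, cfg = matchConfig(), snap_a = NA,
                             snap_b = NA, quarantine = character(0)) {
  if (pairInOverrides(a, b, snap_a, snap_b, cfg))
    return(list(match = TRUE, route = "override"))
  if (cfg@generic_specific_guard &&
      isTRUE(a$is_generic) != isTRUE(b$is_generic))
    return(list(match = FALSE, route = NA_character_))
  ka <- a$kegg_compound; kb <- b$kegg_compound
  if (!is.na(ka) && !is.na(kb)) {
    if (ka == kb) return(list(match = TRUE, route = "kegg_compound"))
    return(list(match = FALSE, route = NA_character_))  # cascade stops here
  }
  for (ns in c("kegg_glycan", "chebi", "pubchem_compound", "cas")) {
    va <- a[[ns]]; vb <- b[[ns]]
    if (!is.na(va) && !is.na(vb) && va == vb)
      return(list(match = TRUE, route = paste0("secondary_id:", ns)))
  }
  na_ <- setdiff(normalizeName(a$names[[1]]), quarantine)
  nb_ <- setdiff(normalizeName(b$names[[1]]), quarantine)
  if (length(intersect(na_, nb_))) {
    ok <- if (cfg@name_requires_formula)
      formulaEqual(a$formula, b$formula, cfg@h_tolerant_formula)
    else TRUE
    if (ok) return(list(match = TRUE, route = "name+formula"))
  }
  list(match = FALSE, route = NA_character_)
}

# ---- union-find -------------------------------------------------------------

# small union-find over 1..n inside an environment (path compression)
newUnionFind <- function(n) {
  env <- new.env(parent = emptyenv())
  env$parent <- seq_len(n)
  env$find <- function(i) {
    p <- env$parent
    root <- i
    while (p[root] != root) root <- p[root]
    while (p[i] != root) {
      nxt <- p[i]; p[i] <- root; i <- nxt
    }
    env$parent <- p
    root
  }
  env$union <- function(i, j) {
    ri <- env$find(i); rj <- env$find(j)
    if (ri != rj) env$parent[max(ri, rj)] <- min(ri, rj)
    invisible(NULL)
  }
  env
}

# ---- metabolite partition ---------------------------------------------------

# flat record table across snapshots with precomputed normalized names
metaboliteRecordTable <- function(snapshots) {
  rows <- lapply(snapshots, function(s) {
    m <- metabolites(s)
    if (nrow(m) == 0) return(NULL)
    m$snapshot <- snapshotName(s)
    m$key <- entityKey(snapshotName(s), m$local_id)
    m$norm_names <- lapply(m$names, normalizeName)
    m
  })
  do.call(rbind, rows)
}

# normalized names mapping to >1 distinct formula within one snapshot
quarantinedNames <- function(recs) {
  if (is.null(recs) || nrow(recs) == 0) return(character(0))
  long <- data.frame(
    snapshot = rep(recs$snapshot, lengths(recs$norm_names)),
    name = unlist(recs$norm_names),
    formula = rep(ifelse(is.na(recs$formula), "<none>", recs$formula),
                  lengths(recs$norm_names)),
    stringsAsFactors = FALSE)
  long <- unique(long)
  tab <- tapply(long$formula, paste(long$snapshot, long$name, sep = "\r"),
                function(f) length(unique(f)))
  keys <- names(tab)[tab > 1]
  unique(vapply(strsplit(keys, "\r", fixed = TRUE), `[`, character(1), 2L))
}

#' Resolve metabolite identity across snapshots
#'
#' Applies [metabolitesMatch()] to candidate pairs within and across all
#' snapshots and takes the transitive closure: matching is treated as an
#' equivalence by connecting matched pairs and taking connected components
#' (union-find), so a match A-B on one identifier and B-C on another places
#' A, B and C in one class. Candidate pairs are generated by blocking on
#' each identifier namespace, on shared normalized names and on override
#' descriptors; every candidate is still decided by the full cascade, so the
#' result equals the brute-force all-pairs closure. Normalized names that
#' map to more than one distinct formula within a snapshot are ambiguous and
#' quarantined from the name route (recorded in
#' \code{attr(, "quarantined_names")}).
#'
#' @param snapshots List of [DatabaseSnapshot] objects (at least two for a
#'   cross-database comparison; within-snapshot duplicates are closed over
#'   as well).
#' @param cfg A [MatchConfig].
#' @return A [MatchPartition] over metabolites. Class representatives are
#'   the lexicographically smallest member keys, so output is deterministic.
#' @export
buildMetabolitePartition <- function(snapshots, cfg = matchConfig()) {
  recs <- metaboliteRecordTable(snapshots)
  if (is.null(recs) || nrow(recs) == 0)
    return(emptyPartition("metabolite"))
  n <- nrow(recs)
  quarantine <- quarantinedNames(recs)
  cand <- candidateMetabolitePairs(recs, cfg, quarantine)
  uf <- newUnionFind(n)
  ev_from <- character(0); ev_to <- character(0); ev_route <- character(0)
  if (nrow(cand)) {
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      res <- metabolitesMatch(recs[i, ], recs[j, ], cfg,
                              snap_a = recs$snapshot[i],
                              snap_b = recs$snapshot[j],
                              quarantine = quarantine)
      if (res$match) {
        uf$union(i, j)
        ev_from <- c(ev_from, min(recs$key[i], recs$key[j]))
        ev_to <- c(ev_to, max(recs$key[i], recs$key[j]))
        ev_route <- c(ev_route, res$route)
      }
    }
  }
  comp <- vapply(seq_len(n), uf$find, integer(1))
  class_id <- stats::ave(recs$key, comp, FUN = min)
  part <- new("MatchPartition", entity_class = "metabolite",
      membership = data.frame(key = recs$key, snapshot = recs$snapshot,
                              local_id = recs$local_id, class_id = class_id,
                              excluded_reason = NA_character_,
                              stringsAsFactors = FALSE),
      evidence = unique(data.frame(from = ev_from, to = ev_to,
                                   route = ev_route,
                                   stringsAsFactors = FALSE)),
      excluded = data.frame(key = character(0), reason = character(0),
                            stringsAsFactors = FALSE))
  attr(part, "quarantined_names") <- quarantine
  part
}

emptyPartition <- function(entity_class) {
  new("MatchPartition", entity_class = entity_class,
      membership = data.frame(key = character(0), snapshot = character(0),
                              local_id = character(0), class_id = character(0),
                              excluded_reason = character(0),
                              stringsAsFactors = FALSE),
      evidence = data.frame(from = character(0), to = character(0),
                            route = character(0), stringsAsFactors = FALSE),
      excluded = data.frame(key = character(0), reason = character(0),
                            stringsAsFactors = FALSE))
}

# candidate pairs by blocking on identifiers, names and override descriptors
candidateMetabolitePairs <- function(recs, cfg, quarantine) {
  n <- nrow(recs)
  pairs_i <- integer(0); pairs_j <- integer(0)
  add_block <- function(groups) {
    for (idx in groups) {
      if (length(idx) < 2) next
      cmb <- utils::combn(idx, 2)
      pairs_i <<- c(pairs_i, cmb[1, ])
      pairs_j <<- c(pairs_j, cmb[2, ])
    }
  }
  for (ns in metNamespaces()) {
    v <- recs[[ns]]
    ok <- which(!is.na(v))
    add_block(split(ok, v[ok]))
  }
  long_idx <- rep(seq_len(n), lengths(recs$norm_names))
  long_name <- unlist(recs$norm_names)
  keep <- !(long_name %in% quarantine)
  add_block(split(long_idx[keep], long_name[keep]))
  ov <- cfg@override_pairs
  if (nrow(ov)) {
    descHits <- function(desc) which(vapply(seq_len(n), function(i)
      matchesDescriptor(recs[i, ], recs$snapshot[i], desc), logical(1)))
    for (k in seq_len(nrow(ov))) {
      ia <- descHits(ov$a[k]); ib <- descHits(ov$b[k])
      if (length(ia) && length(ib)) {
        grid <- expand.grid(i = ia, j = ib)
        grid <- grid[grid$i != grid$j, , drop = FALSE]
        pairs_i <- c(pairs_i, pmin(grid$i, grid$j))
        pairs_j <- c(pairs_j, pmax(grid$i, grid$j))
      }
    }
  }
  unique(data.frame(i = pairs_i, j = pairs_j))
}
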