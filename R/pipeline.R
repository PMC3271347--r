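#' @include synthetic.R
NULL

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

resultRow <- function(res) {
  up <- uniqueCounts(res)
  hist <- occurrenceHistogram(res)
  excl <- res@excluded
  data.frame(
    union = unionSize(res),
    consensus_count = res@consensus_count, consensus_pct = consensusPct(res),
    majority_count = res@majority_count, majority_pct = majorityPct(res),
    majority_threshold = res@majority_threshold,
    unique_total = sum(up),
    unique_pct = percentRound(sum(up), unionSize(res)),
    histogram = paste(sprintf("%s:%d", names(hist), hist), collapse = ","),
    unique_per_snapshot = paste(sprintf("%s:%d", names(up), up),
                                collapse = ","),
    excluded = paste(sprintf("%s:%d", names(excl), excl), collapse = ","),
    stringsAsFactors = FALSE)
}

partitionDump <- function(partition) {
  mb <- membership(partition)
  ev <- evidence(partition)
  route_of <- stats::setNames(ev$route, paste(ev$from, ev$to))
  reps <- mb$class_id
  route <- route_of[paste(pmin(reps, mb$key), pmax(reps, mb$key))]
  out <- data.frame(class_id = mb$class_id,
                    entity_class = partition@entity_class,
                    snapshot = mb$snapshot, local_id = mb$local_id,
                    excluded_reason = mb$excluded_reason,
                    route_evidence = unname(route),
                    stringsAsFactors = FALSE)
  out <- out[order(out$class_id, mb$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

renderReactionCell <- function(row, name_of) {
  nm <- function(s) paste(sort(unname(name_of[names(s)])), collapse = " + ")
  paste(nm(row$side_a[[1]]), "<=>", nm(row$side_b[[1]]))
}

#' Export the reaction alignment overview
#'
#' One row per countable reaction class, aligned across snapshots: for each
#' snapshot the rendered reaction ("A + B <=> C"), its EC numbers, gene
#' identifiers and pathway names, or empty cells when the snapshot lacks
#' the reaction. Rows are ordered by descending agreement count, then class
#' id. Degenerate and otherwise excluded reactions are reported separately
#' with reason codes.
#'
#' @param reaction_partition A reaction [MatchPartition].
#' @param snapshots The snapshots it was built from.
#' @param path Optional TSV output path (the excluded sheet goes to
#'   \code{<path>} with suffix \code{_excluded}).
#' @return List of two data.frames, \code{alignment} and \code{excluded}
#'   (returned invisibly when \code{path} is given).
#' @export
exportAlignment <- function(reaction_partition, snapshots, path = NULL) {
  nms <- sort(vapply(snapshots, snapshotName, character(1)))
  snap_by <- stats::setNames(snapshots,
                             vapply(snapshots, snapshotName, character(1)))
  mb <- membership(reaction_partition)
  ok <- is.na(mb$excluded_reason)
  cells <- new.env(parent = emptyenv())
  for (nm in nms) {
    s <- snap_by[[nm]]
    r <- reactions(s)
    m <- metabolites(s)
    name_of <- stats::setNames(vapply(m$names, `[`, character(1), 1L),
                               m$local_id)
    p <- pathways(s)
    pname_of <- stats::setNames(p$name, p$local_id)
    g <- genes(s)
    gid_of <- stats::setNames(ifelse(is.na(g$gene_id), g$local_id,
                                     g$gene_id), g$local_id)
    rows <- mb[ok & mb$snapshot == nm, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      rr <- r[match(rows$local_id[i], r$local_id), , drop = FALSE]
      cell <- list(
        reaction = renderReactionCell(rr, name_of),
        ecs = joinSet(rr$ecs[[1]]),
        genes = joinSet(unname(gid_of[rr$genes[[1]]])),
        pathways = joinSet(unname(pname_of[rr$pathways[[1]]])))
      k <- paste(rows$class_id[i], nm, sep = "\r")
      prev <- get0(k, envir = cells)
      if (is.null(prev)) assign(k, cell, envir = cells)
    }
  }
  class_ids <- sort(unique(mb$class_id[ok]))
  agree <- vapply(class_ids, function(cl)
    length(unique(mb$snapshot[ok & mb$class_id == cl])), integer(1))
  rows <- lapply(seq_along(class_ids), function(i) {
    out <- data.frame(class_id = class_ids[i],
                      agreement_count = agree[i], stringsAsFactors = FALSE)
    for (nm in nms) {
      cell <- get0(paste(class_ids[i], nm, sep = "\r"), envir = cells)
      out[[paste0(nm, "_reaction")]] <- cell$reaction %||% ""
      out[[paste0(nm, "_ecs")]] <- cell$ecs %||% ""
      out[[paste0(nm, "_genes")]] <- cell$genes %||% ""
      out[[paste0(nm, "_pathways")]] <- cell$pathways %||% ""
    }
    out
  })
  alignment <- do.call(rbind, rows)
  if (!is.null(alignment)) {
    alignment <- alignment[order(-alignment$agreement_count,
                                 alignment$class_id), , drop = FALSE]
    rownames(alignment) <- NULL
  } else {
    alignment <- data.frame(class_id = character(0),
                            agreement_count = integer(0))
  }
  excl <- mb[!ok, c("snapshot", "local_id", "excluded_reason")]
  excl <- excl[order(excl$snapshot, excl$local_id), , drop = FALSE]
  rownames(excl) <- NULL
  if (!is.null(path)) {
    writeTSV(alignment, path)
    writeTSV(excl, sub("(\\.[a-z]+)?$", "_excluded.tsv",
                       sub("\\.tsv$", "", path)))
    return(invisible(list(alignment = alignment, excluded = excl)))
  }
  list(alignment = alignment, excluded = excl)
}

validateConfig <- function(cfg) {
  if (is.null(cfg$snapshots) || length(cfg$snapshots) < 2)
    stop("config field 'snapshots' must list at least two snapshots",
         call. = FALSE)
  for (i in seq_along(cfg$snapshots)) {
    entry <- cfg$snapshots[[i]]
    path <- if (is.character(entry)) entry else entry$path
    if (is.null(path))
      stop(sprintf("config field 'snapshots[%d].path' is missing", i),
           call. = FALSE)
    if (!file.exists(path))
      stop("input snapshot not found: ", path, call. = FALSE)
  }
  modes <- cfg$modes %||% "global"
  bad <- setdiff(modes, c("global", "pairwise", "core", "pathway"))
  if (length(bad))
    stop("config field 'modes' contains unknown mode(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if ("pathway" %in% modes && is.null(cfg$pathway_scope))
    stop("config field 'pathway_scope' is required for mode 'pathway'",
         call. = FALSE)
  invisible(TRUE)
}

#' Run the full comparison pipeline from a config
#'
#' Loads the snapshots named in the config, applies identifier updates and
#' set-reaction expansion, runs the requested comparison modes and writes
#' all artifacts (per-entity summaries as TSV and JSON, pairwise matrices,
#' combination breakdowns, the alignment overview, partition dumps and a
#' run log) into the output directory. Outputs are fully deterministic:
#' identical config produces byte-identical artifacts.
#'
#' @param config Path to a YAML config or an equivalent list. Fields:
#'   \code{snapshots} (list of \code{path} entries), optional
#'   \code{update_tables} (directory of per-namespace TSVs),
#'   \code{category_mapping} (TSV), \code{match} (block for
#'   [matchConfigFromList()]), \code{expand_mode}, \code{modes} (subset of
#'   global/pairwise/core/pathway), \code{pathway_scope},
#'   \code{pathway_aliases}, \code{core} (\code{categories},
#'   \code{drop_macromolecular}, \code{drop_transport}),
#'   \code{majority_threshold}, \code{out_dir}.
#' @param out_dir Overrides the config's output directory.
#' @return Invisibly, the list of comparison results per mode.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  validateConfig(config)
  out_dir <- out_dir %||% config$out_dir %||% "pathcompare_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- matchConfigFromList(config$match %||% list())
  expand_mode <- config$expand_mode %||% "first_member"
  thr <- config$majority_threshold %||% 3L

  snaps <- lapply(config$snapshots, function(entry) {
    path <- if (is.character(entry)) entry else entry$path
    nm <- if (is.list(entry)) entry$name else NULL
    readSnapshot(path, name = nm)
  })
  if (!is.null(config$update_tables)) {
    upd <- readUpdateTables(config$update_tables)
    snaps <- lapply(snaps, applyIdentifierUpdates, tables = upd)
  }
  if (!is.null(config$category_mapping))
    snaps <- lapply(snaps, assignCategories,
                    mapping = config$category_mapping)
  snaps <- lapply(snaps, expandGenericReactions, mode = expand_mode)

  modes <- config$modes %||% "global"
  all_results <- list()
  summary_json <- list()

  if ("global" %in% modes) {
    cmp <- compareSnapshots(snaps, cfg = cfg, majority_threshold = thr)
    all_results$global <- cmp
    for (cl in names(cmp$results)) {
      row <- resultRow(cmp$results[[cl]])
      writeTSV(row, file.path(out_dir, sprintf("summary_%s.tsv", cl)))
      summary_json[[cl]] <- as.list(row)
    }
    for (cl in names(cmp$partitions))
      writeTSV(partitionDump(cmp$partitions[[cl]]),
               file.path(out_dir, sprintf("partition_%s.tsv", cl)))
    exportAlignment(cmp$partitions$reaction, snaps,
                    file.path(out_dir, "alignment_overview.tsv"))
    writeTSV(as.data.frame(combinationGeneEC(
      snaps, cmp$partitions$gene, cmp$partitions$ec)),
      file.path(out_dir, "combination_gene_ec.tsv"))
    writeTSV(as.data.frame(combinationReactionGeneEC(snaps,
                                                     cmp$partitions)),
             file.path(out_dir, "combination_reaction_gene_ec.tsv"))
  }
  if ("pairwise" %in% modes) {
    for (cl in c("gene", "ec", "metabolite", "reaction")) {
      pm <- pairwiseCompare(snaps, cl, cfg = cfg)
      writeTSV(data.frame(snapshot = rownames(pm), pm,
                          check.names = FALSE),
               file.path(out_dir, sprintf("pairwise_%s.tsv", cl)))
      all_results$pairwise[[cl]] <- pm
    }
  }
  if ("core" %in% modes) {
    core_cfg <- config$core %||% list()
    res <- restrictedCompare(
      snaps, categories = unlist(core_cfg$categories) %||% coreCategories(),
      drop_macromolecular = unlist(core_cfg$drop_macromolecular) %||%
        character(0),
      drop_transport = core_cfg$drop_transport %||% TRUE,
      cfg = cfg, majority_threshold = thr)
    all_results$core <- res
    for (cl in names(res$results))
      writeTSV(resultRow(res$results[[cl]]),
               file.path(out_dir, sprintf("summary_core_%s.tsv", cl)))
  }
  if ("pathway" %in% modes) {
    res <- restrictedCompare(
      snaps, pathway = config$pathway_scope,
      pathway_aliases = config$pathway_aliases, cfg = cfg,
      majority_threshold = thr)
    all_results$pathway <- res
    for (cl in names(res$results))
      writeTSV(resultRow(res$results[[cl]]),
               file.path(out_dir, sprintf("summary_pathway_%s.tsv", cl)))
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_lines <- c(
    sprintf("PathCompare %s",
            as.character(utils::packageVersion("PathCompare"))),
    sprintf("snapshots: %s",
            paste(vapply(snaps, snapshotName, character(1)),
                  collapse = ", ")),
    sprintf("modes: %s", paste(modes, collapse = ", ")),
    sprintf("ignore_metabolites: %s",
            paste(cfg@ignore_metabolites, collapse = ", ")),
    sprintf("majority_threshold: %d", as.integer(thr)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(all_results)
}

#' Generate and write synthetic snapshots
#'
#' Generates a ground truth and derives one snapshot per profile, writing
#' each snapshot as interchange JSON, its truth ledger as TSV, and the
#' truth's identifier update tables. Deterministic in the seeds: repeated
#' runs produce byte-identical directories.
#'
#' @param out_dir Output directory.
#' @param profiles Named list of [PerturbationProfile] objects (names
#'   become snapshot names).
#' @param n_reactions,n_pathways,truth_seed Ground-truth parameters.
#' @return Invisibly, list with the truth and the derived snapshot/ledger
#'   pairs.
#' @export
simulateSnapshots <- function(out_dir, profiles, n_reactions = 60,
                              n_pathways = 6, truth_seed = 1L) {
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generateGroundTruth(n_reactions = n_reactions,
                               n_pathways = n_pathways, seed = truth_seed)
  writeUpdateTables(truth@update_tables,
                    file.path(out_dir, "update_tables"))
  derived <- list()
  for (nm in names(profiles)) {
    d <- deriveSnapshot(truth, profiles[[nm]], nm)
    writeSnapshot(d$snapshot, file.path(out_dir, paste0(nm, ".json")))
    writeTruthLedger(d$ledger, file.path(out_dir,
                                         paste0(nm, "_ledger.tsv")))
    derived[[nm]] <- d
  }
  invisible(list(truth = truth, derived = derived))
}
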