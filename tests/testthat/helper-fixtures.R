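# ---- hand-built fixture helpers --------------------------------------------

# quick metabolite table from per-metabolite argument lists
metTable <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    df <- data.frame(
      local_id = r$local_id,
      formula = r$formula %||% NA_character_,
      charge = r$charge %||% NA_integer_,
      compartment = r$compartment %||% NA_character_,
      kegg_compound = r$kegg_compound %||% NA_character_,
      kegg_glycan = r$kegg_glycan %||% NA_character_,
      chebi = r$chebi %||% NA_character_,
      pubchem_compound = r$pubchem_compound %||% NA_character_,
      cas = r$cas %||% NA_character_,
      is_generic = r$is_generic %||% FALSE,
      is_protein = r$is_protein %||% FALSE,
      stringsAsFactors = FALSE)
    df$names <- list(r$names %||% r$local_id)
    df$instance_ids <- list(r$instance_ids %||% character(0))
    df
  }))
}

rxnTable <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    df <- data.frame(local_id = r$local_id,
                     reversible = r$reversible %||% NA,
                     is_set_reaction = r$is_set_reaction %||% FALSE,
                     expansion_flagged = FALSE, stringsAsFactors = FALSE)
    df$side_a <- list(r$side_a)
    df$side_b <- list(r$side_b)
    df$genes <- list(r$genes %||% character(0))
    df$ecs <- list(r$ecs %||% character(0))
    df$pathways <- list(r$pathways %||% character(0))
    df
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- random fixtures for fuzz/oracle tests ----------------------------------

# snapshots whose metabolites draw identifiers/names/formulas from small
# shared pools, so every cascade route (and the kegg stop rule) is exercised
randomMetaboliteSnapshots <- function(seed, n_snapshots = 3,
                                      n_per_snapshot = 15) {
  set.seed(seed)
  kegg_pool <- sprintf("C0%04d", 1:8)
  chebi_pool <- sprintf("CHEBI:%d", 101:108)
  cas_pool <- sprintf("%d-%02d-%d", 5001:5008, 11:18, 1:8)
  glycan_pool <- sprintf("G%05d", 1:4)
  name_pool <- sprintf("compound %s", letters[1:10])
  formula_pool <- sprintf("C%dH%dO%d", 2:7, 4:9, 1:6)
  maybe <- function(pool, p_na) {
    v <- sample(pool, 1)
    if (runif(1) < p_na) NA_character_ else v
  }
  snaps <- lapply(seq_len(n_snapshots), function(s) {
    rows <- lapply(seq_len(n_per_snapshot), function(i) {
      df <- data.frame(
        local_id = sprintf("m%02d", i),
        formula = maybe(formula_pool, 0.3),
        charge = NA_integer_, compartment = NA_character_,
        kegg_compound = maybe(kegg_pool, 0.45),
        kegg_glycan = maybe(glycan_pool, 0.8),
        chebi = maybe(chebi_pool, 0.6),
        pubchem_compound = NA_character_,
        cas = maybe(cas_pool, 0.6),
        is_generic = runif(1) < 0.1, is_protein = FALSE,
        stringsAsFactors = FALSE)
      df$names <- list(sample(name_pool, sample(1:2, 1)))
      df$instance_ids <- list(character(0))
      df
    })
    databaseSnapshot(sprintf("S%d", s), metabolites = do.call(rbind, rows))
  })
  snaps
}

# O(n^2) all-pairs match graph + graph components: the independent oracle
# for partition building. The ambiguous-name rule (a normalized name tied
# to more than one formula within a snapshot is barred from name matching)
# is re-derived here from scratch.
bruteForceQuarantine <- function(snapshots) {
  bad <- character(0)
  for (s in snapshots) {
    m <- metabolites(s)
    seen <- list()
    for (i in seq_len(nrow(m))) {
      f <- if (is.na(m$formula[i])) "<none>" else m$formula[i]
      for (nm in unique(normalizeName(m$names[[i]])))
        seen[[nm]] <- union(seen[[nm]], f)
    }
    bad <- union(bad, names(seen)[lengths(seen) > 1])
  }
  bad
}

bruteForceMetabolitePartition <- function(snapshots, cfg) {
  recs <- do.call(rbind, lapply(snapshots, function(s) {
    m <- metabolites(s)
    if (nrow(m) == 0) return(NULL)
    m$snapshot <- snapshotName(s)
    m$key <- paste0(snapshotName(s), "::", m$local_id)
    m
  }))
  quarantine <- bruteForceQuarantine(snapshots)
  n <- nrow(recs)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      res <- metabolitesMatch(recs[i, ], recs[j, ], cfg,
                              snap_a = recs$snapshot[i],
                              snap_b = recs$snapshot[j],
                              quarantine = quarantine)
      if (res$match) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  split(recs$key, comp)
}

# canonical form of a partition: sorted list of sorted member-key vectors
canonicalClasses <- function(classes) {
  cl <- unname(lapply(classes, function(x) sort(unname(x))))
  cl[order(vapply(cl, `[`, character(1), 1L))]
}

partitionClasses <- function(partition, countable_only = FALSE) {
  mb <- membership(partition)
  if (countable_only) mb <- mb[is.na(mb$excluded_reason), , drop = FALSE]
  canonicalClasses(split(mb$key, mb$class_id))
}

# ---- pipeline fixture shared by pipeline and acceptance tests --------------

write_pipeline_inputs <- function(dir, p_cov = 0.85, n_reactions = 40) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generateGroundTruth(n_reactions, 4, seed = 17)
  for (i in 1:3) {
    d <- deriveSnapshot(truth, perturbationProfile(
      p_cov = p_cov, p_id_drop = c(kegg_compound = 0.2),
      p_flip_direction = 0.2, seed = 100 + i), sprintf("db%d", i))
    writeSnapshot(d$snapshot, file.path(dir, sprintf("db%d.json", i)))
  }
  writeUpdateTables(truth@update_tables, file.path(dir, "updates"))
  cfgfile <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(
    snapshots = lapply(sprintf("db%d.json", 1:3), function(f)
      list(path = file.path(dir, f))),
    update_tables = file.path(dir, "updates"),
    modes = list("global", "pairwise"),
    majority_threshold = 2,
    out_dir = file.path(dir, "out")), cfgfile)
  cfgfile
}

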