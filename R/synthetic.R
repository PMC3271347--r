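#' @include restricted.R
NULL

# fixed currency/cofactor metabolites shared by many reactions
currencyTable <- function() {
  df <- data.frame(
    local_id = c("cur_h2o", "cur_hplus", "cur_e", "cur_atp", "cur_adp",
                 "cur_nad", "cur_nadh", "cur_nadp", "cur_nadph", "cur_fad",
                 "cur_fadh2", "cur_pi", "cur_coa", "cur_itp", "cur_idp"),
    kegg = c("C00001", "C00080", "C05359", "C00002", "C00008", "C00003",
             "C00004", "C00006", "C00005", "C00016", "C01352", "C00009",
             "C00010", "C00081", "C00104"),
    name = c("H2O", "H+", "e-", "ATP", "ADP", "NAD+", "NADH", "NADP+",
             "NADPH", "FAD", "FADH2", "Orthophosphate", "CoA", "ITP",
             "IDP"),
    formula = c("H2O", "H", "e", "C10H16N5O13P3", "C10H15N5O10P2",
                "C21H28N7O14P2", "C21H29N7O14P2", "C21H29N7O17P3",
                "C21H30N7O17P3", "C27H33N9O15P2", "C27H35N9O15P2",
                "H3PO4", "C21H36N7O16P3S", "C10H16N5O14P3",
                "C10H15N5O11P2"),
    stringsAsFactors = FALSE)
  df
}

# cofactor pairs cycled along reaction chains (consumed -> produced)
cofactorPairs <- function() {
  list(c("cur_atp", "cur_adp"), c("cur_nad", "cur_nadh"),
       c("cur_nadp", "cur_nadph"), c("cur_fad", "cur_fadh2"))
}

truthCategoryCycle <- function() {
  c(coreCategories(), "glycan biosynthesis and metabolism",
    "xenobiotics biodegradation and metabolism", "miscellaneous")
}

#' Generate a ground-truth metabolic network
#'
#' Builds a fully identified reference network: pathways partition the
#' reactions into linear conversion chains over unique main metabolites,
#' every reaction turns over one of four cofactor pairs (ATP/ADP, NAD+/NADH,
#' NADP+/NADPH, FAD/FADH2), protons and water appear on a regular subset of
#' reactions, and a small number of ATP-driven transport reactions move a
#' metabolite between compartments. Every metabolite carries a full
#' identifier bundle (synthetic accessions in the shared pseudo-namespace),
#' a unique name and a unique formula; generic classes with instance lists
#' and protein-flagged participants are planted at low rates. Chains of
#' three consecutive reactions are annotated as routes eligible for lumping
#' (at least one per pathway). The same seed always yields the identical
#' truth.
#'
#' @param n_reactions Total number of reactions (>= 1).
#' @param n_pathways Number of pathways the reactions are divided over.
#' @param seed Integer seed.
#' @return A [GroundTruth].
#' @export
generateGroundTruth <- function(n_reactions = 60, n_pathways = 6,
                                seed = 1L) {
  stopifnot(n_reactions >= 1, n_pathways >= 1)
  set.seed(as.integer(seed))
  cur <- currencyTable()
  n_transport <- if (n_reactions >= 25) n_reactions %/% 25 else 0L
  n_chain <- n_reactions - n_transport
  n_pathways <- min(n_pathways, n_chain)
  chain_len <- diff(floor(seq(0, n_chain, length.out = n_pathways + 1)))
  n_main <- sum(chain_len + 1L)

  mains <- data.frame(
    local_id = sprintf("M%04d", seq_len(n_main)),
    stringsAsFactors = FALSE)
  mains$kegg <- sprintf("C1%04d", seq_len(n_main))
  mains$name <- sprintf("Metabolite-%04d", seq_len(n_main))
  mains$formula <- sprintf("C%dH%dN%dO%d", 3 + (seq_len(n_main) %% 25),
                           10 + seq_len(n_main), 1 + (seq_len(n_main) %% 4),
                           2 + (seq_len(n_main) %% 7))
  mains$is_protein <- seq_len(n_main) %% 37 == 0

  met <- data.frame(
    local_id = c(cur$local_id, mains$local_id),
    formula = c(cur$formula, mains$formula),
    charge = 0L,
    compartment = "c",
    kegg_compound = c(cur$kegg, mains$kegg),
    kegg_glycan = NA_character_,
    chebi = sprintf("CHEBI:%d", 10000 + seq_len(nrow(cur) + n_main)),
    pubchem_compound = sprintf("%d", 50000 + seq_len(nrow(cur) + n_main)),
    cas = sprintf("%d-%02d-%d", 1000 + seq_len(nrow(cur) + n_main),
                  seq_len(nrow(cur) + n_main) %% 100,
                  seq_len(nrow(cur) + n_main) %% 10),
    is_generic = FALSE,
    is_protein = c(rep(FALSE, nrow(cur)), mains$is_protein),
    stringsAsFactors = FALSE)
  met$names <- as.list(c(cur$name, mains$name))
  met$instance_ids <- rep(list(character(0)), nrow(met))
  glyc <- which(seq_len(nrow(met)) %% 20 == 0)
  met$kegg_glycan[glyc] <- sprintf("G%05d", seq_along(glyc))

  # generic classes over consecutive main metabolites
  n_generic <- max(1L, n_main %/% 12L)
  gen_rows <- lapply(seq_len(n_generic), function(j) {
    members <- mains$local_id[((j - 1) * 3 + 1):min(j * 3, n_main)]
    df <- data.frame(
      local_id = sprintf("CL%03d", j), formula = NA_character_,
      charge = NA_integer_, compartment = "c",
      kegg_compound = sprintf("C2%04d", j), kegg_glycan = NA_character_,
      chebi = NA_character_, pubchem_compound = NA_character_,
      cas = NA_character_, is_generic = TRUE, is_protein = FALSE,
      stringsAsFactors = FALSE)
    df$names <- list(sprintf("a class-%03d compound", j))
    df$instance_ids <- list(members)
    df
  })
  # mitochondrial copies of one main per transport reaction
  transported <- if (n_transport > 0) mains$local_id[seq_len(n_transport)]
    else character(0)
  mito_rows <- lapply(transported, function(id) {
    src <- met[met$local_id == id, , drop = FALSE]
    src$local_id <- paste0(id, "m")
    src$compartment <- "m"
    src
  })
  met <- do.call(rbind, c(list(met), gen_rows, mito_rows))
  rownames(met) <- NULL

  # pathways
  pw <- data.frame(
    local_id = sprintf("PW%02d", seq_len(n_pathways + (n_transport > 0))),
    stringsAsFactors = FALSE)
  pw$name <- sprintf("pathway %02d", seq_len(nrow(pw)))
  cats <- truthCategoryCycle()
  pw$category <- cats[(seq_len(nrow(pw)) - 1L) %% length(cats) + 1L]
  if (n_transport > 0) {
    pw$name[nrow(pw)] <- "transport pathway"
    pw$category[nrow(pw)] <- "transport"
  }

  # genes and EC pool
  n_genes <- max(3L, round(0.8 * n_reactions))
  gene_pool <- sprintf("%d", 1000 + seq_len(n_genes))

  pairs <- cofactorPairs()
  rxn_rows <- list()
  route_rows <- list()
  t <- 0L
  m_off <- 0L
  for (p in seq_len(n_pathways)) {
    len <- chain_len[p]
    chain <- mains$local_id[(m_off + 1):(m_off + len + 1)]
    m_off <- m_off + len + 1L
    for (j in seq_len(len)) {
      t <- t + 1L
      cof <- pairs[[(t - 1L) %% length(pairs) + 1L]]
      sa <- stats::setNames(c(1, 1), c(chain[j], cof[1]))
      sb <- stats::setNames(c(1, 1), c(chain[j + 1], cof[2]))
      if (t %% 3 == 0) sb <- c(sb, cur_hplus = 1)
      if (t %% 4 == 0) sa <- c(sa, cur_h2o = 1)
      if (t %% 5 == 0) sb <- c(sb, cur_pi = 1)
      df <- data.frame(
        local_id = sprintf("R%04d", t), reversible = t %% 2 == 0,
        is_set_reaction = FALSE, expansion_flagged = FALSE,
        stringsAsFactors = FALSE)
      df$side_a <- list(sa[order(names(sa))])
      df$side_b <- list(sb[order(names(sb))])
      df$genes <- list(sort(sample(gene_pool, 1 + stats::rbinom(1, 1, 0.4))))
      df$ecs <- list(sprintf("%d.%d.%d.%d", 1 + (t %% 6), 1 + (t %% 3),
                             1 + (t %% 5), 1 + (t %% 9)))
      df$pathways <- list(pw$local_id[p])
      rxn_rows[[t]] <- df
    }
    if (len >= 3) {
      start <- t - len + 1L
      rdf <- data.frame(route_id = sprintf("route_%s", pw$local_id[p]),
                        stringsAsFactors = FALSE)
      rdf$reaction_ids <- list(sprintf("R%04d", start:(start + 2L)))
      route_rows[[length(route_rows) + 1L]] <- rdf
    }
  }
  for (k in seq_len(n_transport)) {
    t <- t + 1L
    id <- transported[k]
    df <- data.frame(
      local_id = sprintf("R%04d", t), reversible = FALSE,
      is_set_reaction = FALSE, expansion_flagged = FALSE,
      stringsAsFactors = FALSE)
    sa <- stats::setNames(c(1, 1), c(id, "cur_atp"))
    sb <- stats::setNames(c(1, 1), c(paste0(id, "m"), "cur_adp"))
    df$side_a <- list(sa[order(names(sa))])
    df$side_b <- list(sb[order(names(sb))])
    df$genes <- list(sort(sample(gene_pool, 1)))
    df$ecs <- list(character(0))
    df$pathways <- list(pw$local_id[nrow(pw)])
    rxn_rows[[t]] <- df
  }
  rxn <- do.call(rbind, rxn_rows)

  gene_ids <- sort(unique(unlist(rxn$genes)))
  gtab <- data.frame(local_id = gene_ids, gene_id = gene_ids,
                     stringsAsFactors = FALSE)

  snap <- databaseSnapshot("truth", genes = gtab, metabolites = met,
                           reactions = rxn, pathways = pw)
  # superseded accessions: X-prefixed forms of every current compound id
  old_of <- sprintf("X%05d", seq_len(nrow(met)))
  cur_ids <- met$kegg_compound
  keep <- !is.na(cur_ids)
  upd <- updateTables(
    transferred = list(
      kegg_compound = stats::setNames(cur_ids[keep], old_of[keep]),
      gene = stats::setNames(gene_ids,
                             sprintf("%d", 500000 + as.integer(gene_ids)))),
    obsolete = list(kegg_compound = sprintf("C9%04d", 1:10)))
  routes <- if (length(route_rows)) do.call(rbind, route_rows) else {
    rdf <- data.frame(route_id = character(0), stringsAsFactors = FALSE)
    rdf$reaction_ids <- list()
    rdf
  }
  alt <- data.frame(from = c("cur_atp", "cur_adp"),
                    to = c("cur_itp", "cur_idp"), stringsAsFactors = FALSE)
  new("GroundTruth", snapshot = snap, routes = routes, update_tables = upd,
      alt_pairs = alt,
      truth_hash = sprintf("gt-%d-%d-%d", as.integer(seed),
                           as.integer(n_reactions), as.integer(n_pathways)),
      seed = as.integer(seed))
}

#' Construct a perturbation profile
#'
#' All probabilities act independently per eligible entity; the default
#' profile (\code{p_cov = 1}, everything else 0) reproduces the truth
#' exactly up to local-id relabeling. See [PerturbationProfile] for the
#' meaning of each rate.
#'
#' @param p_cov Reaction inclusion probability.
#' @param p_id_drop Either a single rate applied to every identifier
#'   namespace or a named vector over
#'   \code{c(metNamespaces(), "gene")}.
#' @param p_name_variant,p_proton_shift,p_lump,p_alt_substrate,p_generic,p_obsolete_inject,p_flip_direction,p_balance_h2o_hplus,p_drop_pathway
#'   Perturbation rates in \code{[0, 1]}.
#' @param seed Integer seed used when deriving a snapshot.
#' @return A [PerturbationProfile].
#' @export
perturbationProfile <- function(p_cov = 1, p_id_drop = 0,
                                p_name_variant = 0, p_proton_shift = 0,
                                p_lump = 0, p_alt_substrate = 0,
                                p_generic = 0, p_obsolete_inject = 0,
                                p_flip_direction = 0,
                                p_balance_h2o_hplus = 0,
                                p_drop_pathway = 0, seed = 1L) {
  spaces <- c(metNamespaces(), "gene")
  if (is.null(names(p_id_drop))) {
    p_id_drop <- stats::setNames(rep(p_id_drop[1], length(spaces)), spaces)
  } else {
    full <- stats::setNames(rep(0, length(spaces)), spaces)
    full[names(p_id_drop)] <- p_id_drop
    p_id_drop <- full
  }
  new("PerturbationProfile", p_cov = p_cov, p_id_drop = p_id_drop,
      p_name_variant = p_name_variant, p_proton_shift = p_proton_shift,
      p_lump = p_lump, p_alt_substrate = p_alt_substrate,
      p_generic = p_generic, p_obsolete_inject = p_obsolete_inject,
      p_flip_direction = p_flip_direction,
      p_balance_h2o_hplus = p_balance_h2o_hplus,
      p_drop_pathway = p_drop_pathway, seed = as.integer(seed))
}

#' Read a perturbation profile from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [perturbationProfile()].
#' @return A [PerturbationProfile].
#' @export
perturbationProfileFromYAML <- function(path) {
  x <- yaml::read_yaml(path)
  args <- x[intersect(names(x), names(formals(perturbationProfile)))]
  if (!is.null(args$p_id_drop) && is.list(args$p_id_drop))
    args$p_id_drop <- unlist(args$p_id_drop)
  do.call(perturbationProfile, args)
}

# symbolic net reaction of a chain: sum the sides, cancel shared species
netReaction <- function(sides_a, sides_b) {
  tot <- function(sides) {
    all <- unlist(sides)
    v <- tapply(all, names(all), sum)
    stats::setNames(as.numeric(v), names(v))
  }
  a <- tot(sides_a); b <- tot(sides_b)
  common <- intersect(names(a), names(b))
  for (sp in common) {
    cancel <- min(a[[sp]], b[[sp]])
    a[[sp]] <- a[[sp]] - cancel
    b[[sp]] <- b[[sp]] - cancel
  }
  list(a = a[a > 0][order(names(a[a > 0]))],
       b = b[b > 0][order(names(b[b > 0]))])
}

#' Derive a perturbed database snapshot from a ground truth
#'
#' Applies, in a fixed order, the perturbations of \code{profile} to the
#' truth network: coverage subsetting, route lumping (a fully covered
#' eligible chain is replaced by its net reaction with intermediates
#' canceled), direction flips, proton/water balancing edits,
#' alternative-cosubstrate duplicates (ATP/ADP swapped to ITP/IDP),
#' generic-class substitution, pathway-assignment dropout, and per-record
#' identifier dropout, obsolete-identifier injection, name variants and
#' protonation shifts. Local ids are relabeled per snapshot so that nothing
#' can match on them. Every emitted entity is recorded in the returned
#' [TruthLedger] with its truth identity and the perturbation tags applied.
#' The derivation is fully deterministic in \code{profile@seed}.
#'
#' @param truth A [GroundTruth].
#' @param profile A [PerturbationProfile].
#' @param name Name for the derived snapshot.
#' @return List with elements \code{snapshot} ([DatabaseSnapshot]) and
#'   \code{ledger} ([TruthLedger]).
#' @export
deriveSnapshot <- function(truth, profile, name) {
  stopifnot(is(truth, "GroundTruth"), is(profile, "PerturbationProfile"))
  set.seed(profile@seed)
  ts <- truth@snapshot
  tr <- reactions(ts)
  tm <- metabolites(ts)
  rownames(tm) <- tm$local_id

  incl <- stats::runif(nrow(tr)) < profile@p_cov
  included_ids <- tr$local_id[incl]

  # route lumping over fully covered eligible chains
  lumped_members <- character(0)
  lump_rows <- list()
  routes <- truth@routes
  for (k in seq_len(nrow(routes))) {
    members <- routes$reaction_ids[[k]]
    if (!all(members %in% included_ids)) next
    if (stats::runif(1) >= profile@p_lump) next
    rows <- tr[match(members, tr$local_id), , drop = FALSE]
    net <- netReaction(rows$side_a, rows$side_b)
    df <- rows[1, , drop = FALSE]
    df$local_id <- routes$route_id[k]
    df$side_a <- list(net$a)
    df$side_b <- list(net$b)
    df$genes <- list(sort(unique(unlist(rows$genes))))
    df$ecs <- list(sort(unique(unlist(rows$ecs))))
    df$pathways <- list(sort(unique(unlist(rows$pathways))))
    lump_rows[[length(lump_rows) + 1L]] <-
      list(row = df, truth_id = routes$route_id[k], tag = "lump")
    lumped_members <- c(lumped_members, members)
  }

  plain_ids <- setdiff(included_ids, lumped_members)
  rxn_list <- lapply(plain_ids, function(id) {
    list(row = tr[match(id, tr$local_id), , drop = FALSE], truth_id = id,
         tag = character(0))
  })
  rxn_list <- c(rxn_list, lapply(lump_rows, function(l)
    list(row = l$row, truth_id = l$truth_id, tag = l$tag)))

  # instance -> generic class map
  class_of_instance <- character(0)
  gen <- tm[tm$is_generic, , drop = FALSE]
  for (i in seq_len(nrow(gen)))
    for (inst in gen$instance_ids[[i]])
      if (!inst %in% names(class_of_instance))
        class_of_instance[inst] <- gen$local_id[i]

  out_rxns <- list()
  for (entry in rxn_list) {
    row <- entry$row
    tags <- entry$tag
    if (stats::runif(1) < profile@p_flip_direction) {
      tmp <- row$side_a; row$side_a <- row$side_b; row$side_b <- tmp
      tags <- c(tags, "flip")
    }
    if (stats::runif(1) < profile@p_balance_h2o_hplus) {
      sp <- if (stats::runif(1) < 0.5) "cur_hplus" else "cur_h2o"
      side <- if (stats::runif(1) < 0.5) "side_a" else "side_b"
      s <- row[[side]][[1]]
      if (sp %in% names(s)) {
        if (length(s) > 1) {
          s <- s[names(s) != sp]
          tags <- c(tags, "balance_remove")
        }
      } else {
        s[[sp]] <- 1
        tags <- c(tags, "balance_add")
      }
      row[[side]] <- list(s[order(names(s))])
    }
    if (profile@p_generic > 0) {
      for (side in c("side_a", "side_b")) {
        s <- row[[side]][[1]]
        for (sp in names(s)) {
          if (sp %in% names(class_of_instance) &&
              stats::runif(1) < profile@p_generic) {
            cls <- class_of_instance[[sp]]
            coef <- s[[sp]]
            s <- s[names(s) != sp]
            if (cls %in% names(s)) s[[cls]] <- s[[cls]] + coef
            else s[[cls]] <- coef
            row$is_set_reaction <- TRUE
            tags <- c(tags, "generic")
          }
        }
        row[[side]] <- list(s[order(names(s))])
      }
    }
    if (stats::runif(1) < profile@p_drop_pathway) {
      row$pathways <- list(character(0))
      tags <- c(tags, "drop_pathway")
    }
    out_rxns[[length(out_rxns) + 1L]] <-
      list(row = row, truth_id = entry$truth_id, tags = tags)
    if (profile@p_alt_substrate > 0) {
      swaps <- truth@alt_pairs
      present <- any(swaps$from %in% c(names(row$side_a[[1]]),
                                       names(row$side_b[[1]])))
      if (present && stats::runif(1) < profile@p_alt_substrate) {
        alt <- row
        for (side in c("side_a", "side_b")) {
          s <- alt[[side]][[1]]
          hit <- match(names(s), swaps$from)
          names(s)[!is.na(hit)] <- swaps$to[hit[!is.na(hit)]]
          alt[[side]] <- list(s[order(names(s))])
        }
        alt$local_id <- paste0(row$local_id, "_alt")
        out_rxns[[length(out_rxns) + 1L]] <-
          list(row = alt, truth_id = paste0(entry$truth_id, "#alt"),
               tags = c(tags, "alt_substrate"))
      }
    }
  }

  # referenced metabolites (with generic classes' instances kept so the
  # class/instance structure survives validation)
  used_m <- unique(unlist(lapply(out_rxns, function(e)
    c(names(e$row$side_a[[1]]), names(e$row$side_b[[1]])))))
  repeat {
    inst <- unique(unlist(tm$instance_ids[match(used_m, tm$local_id)]))
    grown <- union(used_m, inst)
    if (length(grown) == length(used_m)) break
    used_m <- grown
  }
  used_m <- tm$local_id[tm$local_id %in% used_m]   # truth order
  met_out <- tm[match(used_m, tm$local_id), , drop = FALSE]
  met_tags <- rep(list(character(0)), nrow(met_out))

  rev_kegg <- truth@update_tables@transferred$kegg_compound
  old_of_kegg <- stats::setNames(names(rev_kegg), unname(rev_kegg))
  rev_gene <- truth@update_tables@transferred$gene
  old_of_gene <- stats::setNames(names(rev_gene), unname(rev_gene))

  for (i in seq_len(nrow(met_out))) {
    tg <- character(0)
    for (ns in metNamespaces()) {
      if (!is.na(met_out[[ns]][i]) &&
          stats::runif(1) < profile@p_id_drop[[ns]]) {
        met_out[[ns]][i] <- NA_character_
        tg <- c(tg, paste0("id_drop:", ns))
      }
    }
    if (!is.na(met_out$kegg_compound[i]) &&
        met_out$kegg_compound[i] %in% names(old_of_kegg) &&
        stats::runif(1) < profile@p_obsolete_inject) {
      met_out$kegg_compound[i] <- old_of_kegg[[met_out$kegg_compound[i]]]
      tg <- c(tg, "obsolete_id")
    }
    if (stats::runif(1) < profile@p_name_variant) {
      primary <- met_out$names[[i]][1]
      if (stats::runif(1) < 0.5) {
        variant <- toupper(gsub("-", " ", primary, fixed = TRUE))
        met_out$names[i] <- list(variant)
        tg <- c(tg, "name_variant")
      } else {
        met_out$names[i] <- list(sprintf("trivial name %s x",
                                         met_out$local_id[i]))
        tg <- c(tg, "hard_synonym")
      }
    }
    if (stats::runif(1) < profile@p_proton_shift &&
        !is.na(met_out$formula[i])) {
      counts <- parseFormula(met_out$formula[i])
      h <- if ("H" %in% names(counts)) counts[["H"]] else 0L
      up <- stats::runif(1) < 0.5 || h < 1
      counts["H"] <- h + if (up) 1L else -1L
      counts <- counts[counts > 0]
      met_out$formula[i] <- paste0(names(counts), ifelse(counts == 1, "",
                                                         counts),
                                   collapse = "")
      ch <- met_out$charge[i]
      met_out$charge[i] <- (if (is.na(ch)) 0L else ch) + if (up) 1L else -1L
      met_out$names[i] <- list(c(
        sprintf("%s (%s)", met_out$names[[i]][1], if (up) "1+" else "1-"),
        met_out$names[[i]]))
      tg <- c(tg, "proton_shift")
    }
    met_tags[[i]] <- tg
  }

  # relabel local ids
  m_new <- sprintf("m%04d", seq_len(nrow(met_out)))
  m_map <- stats::setNames(m_new, met_out$local_id)
  met_out$instance_ids <- lapply(met_out$instance_ids, function(x)
    unname(m_map[x[x %in% names(m_map)]]))
  met_truth <- met_out$local_id
  met_out$local_id <- m_new

  used_g <- sort(unique(unlist(lapply(out_rxns, function(e)
    e$row$genes[[1]]))))
  g_new <- sprintf("g%04d", seq_along(used_g))
  g_map <- stats::setNames(g_new, used_g)
  gene_ids <- used_g   # truth gene local_id == entrez id
  g_tags <- rep(list(character(0)), length(used_g))
  for (i in seq_along(gene_ids)) {
    if (stats::runif(1) < profile@p_id_drop[["gene"]]) {
      gene_ids[i] <- NA_character_
      g_tags[[i]] <- c(g_tags[[i]], "id_drop:gene")
    } else if (gene_ids[i] %in% names(old_of_gene) &&
               stats::runif(1) < profile@p_obsolete_inject) {
      gene_ids[i] <- old_of_gene[[gene_ids[i]]]
      g_tags[[i]] <- c(g_tags[[i]], "obsolete_id")
    }
  }
  gene_out <- data.frame(local_id = g_new, gene_id = gene_ids,
                         stringsAsFactors = FALSE)

  used_p <- sort(unique(unlist(lapply(out_rxns, function(e)
    e$row$pathways[[1]]))))
  tp <- pathways(ts)
  p_new <- sprintf("p%02d", seq_along(used_p))
  p_map <- stats::setNames(p_new, used_p)
  pw_out <- tp[match(used_p, tp$local_id), , drop = FALSE]
  pw_out$local_id <- p_new

  r_rows <- lapply(seq_along(out_rxns), function(i) {
    e <- out_rxns[[i]]
    row <- e$row
    relab <- function(s) {
      names(s) <- unname(m_map[names(s)])
      s[order(names(s))]
    }
    row$side_a <- list(relab(row$side_a[[1]]))
    row$side_b <- list(relab(row$side_b[[1]]))
    row$genes <- list(sort(unname(g_map[row$genes[[1]]])))
    row$pathways <- list(sort(unname(p_map[row$pathways[[1]]])))
    row$local_id <- sprintf("r%04d", i)
    row
  })
  rxn_out <- do.call(rbind, r_rows)

  snap <- databaseSnapshot(name, genes = gene_out, metabolites = met_out,
                           reactions = rxn_out, pathways = pw_out)
  entries <- rbind(
    data.frame(entity_class = "metabolite", local_id = m_new,
               truth_id = met_truth,
               tags = vapply(met_tags, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE),
    data.frame(entity_class = "gene", local_id = g_new, truth_id = used_g,
               tags = vapply(g_tags, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE),
    data.frame(entity_class = "reaction",
               local_id = sprintf("r%04d", seq_along(out_rxns)),
               truth_id = vapply(out_rxns, `[[`, character(1), "truth_id"),
               tags = vapply(out_rxns, function(e)
                 paste(e$tags, collapse = ","), character(1)),
               stringsAsFactors = FALSE))
  ledger <- new("TruthLedger", snapshot = name,
                truth_hash = truth@truth_hash, entries = entries)
  list(snapshot = snap, ledger = ledger)
}

#' Ground-truth entity sets behind derived snapshots
#'
#' Reads the membership of each derived snapshot directly off its
#' [TruthLedger] — completely independent of the matcher — yielding the sets
#' of truth identities per snapshot. Feeding the result to [consensus()]
#' gives the exact overlap statistics a perfect matcher would recover.
#'
#' @param ledgers List of [TruthLedger] objects from the same
#'   [GroundTruth].
#' @param entity_class \code{"gene"}, \code{"metabolite"} or
#'   \code{"reaction"}.
#' @return Named list of truth-id sets, one per snapshot.
#' @export
trueOverlap <- function(ledgers, entity_class) {
  stopifnot(length(ledgers) >= 1)
  hashes <- vapply(ledgers, function(l) l@truth_hash, character(1))
  if (length(unique(hashes)) != 1)
    stop("ledgers come from different ground truths", call. = FALSE)
  sets <- lapply(ledgers, function(l) {
    e <- truthEntries(l)
    sort(unique(e$truth_id[e$entity_class == entity_class]))
  })
  names(sets) <- vapply(ledgers, function(l) l@snapshot, character(1))
  sets[order(names(sets))]
}

#' Write a truth ledger to TSV
#'
#' @param ledger A [TruthLedger].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeTruthLedger <- function(ledger, path) {
  e <- truthEntries(ledger)
  e <- e[order(e$entity_class, e$local_id), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
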