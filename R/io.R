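#' @include snapshot.R
NULL

interchangeSchemaVersion <- "1.0"

#' Default identifier syntax patterns
#'
#' Regular expressions each identifier namespace must satisfy when a
#' snapshot is loaded with \code{schema_check = TRUE}. Override individual
#' entries to accommodate local accession schemes.
#'
#' @return Named character vector of regexes for \code{kegg_compound},
#'   \code{kegg_glycan}, \code{chebi}, \code{pubchem_compound}, \code{cas}
#'   and \code{gene}.
#' @export
idPatterns <- function() {
  c(kegg_compound = "^[A-Z][0-9]{5}$",
    kegg_glycan = "^G[0-9]{5}$",
    chebi = "^(CHEBI:)?[0-9]+$",
    pubchem_compound = "^[0-9]+$",
    cas = "^[0-9]{2,7}-[0-9]{2}-[0-9]$",
    gene = "^[0-9]+$")
}

metNamespaces <- function() {
  c("kegg_compound", "kegg_glycan", "chebi", "pubchem_compound", "cas")
}

#' Read a snapshot from the interchange format
#'
#' Accepts either a single interchange JSON document or a directory holding
#' the TSV bundle variant (\code{genes.tsv}, \code{metabolites.tsv},
#' \code{reactions.tsv}, \code{pathways.tsv}; list-valued cells
#' pipe-delimited, reaction sides written \code{"m1:1|m2:2"}). Loading is
#' order-independent: record order in the file does not affect the result.
#' SBML and BioPAX input is refused — export those to the interchange format
#' first.
#'
#' @param path Path to a \code{.json} file or a TSV bundle directory.
#' @param schema_check Also check \code{schema_version} and identifier
#'   syntax against \code{id_patterns}?
#' @param id_patterns Named regexes, see [idPatterns()].
#' @param name Override the snapshot name stored in the file (for TSV
#'   bundles the default name is the directory's basename).
#' @return A validated [DatabaseSnapshot].
#' @seealso [writeSnapshot()]
#' @export
readSnapshot <- function(path, schema_check = TRUE,
                         id_patterns = idPatterns(), name = NULL) {
  if (!file.exists(path))
    stop("snapshot file not found: ", path, call. = FALSE)
  if (dir.exists(path)) {
    snap <- readSnapshotTSV(path, name = name %||% basename(path))
  } else {
    refuseForeignFormats(path)
    doc <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = FALSE),
      error = function(e) stop("malformed interchange JSON in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (schema_check && !is.null(doc$schema_version) &&
        doc$schema_version != interchangeSchemaVersion)
      stop(sprintf("unsupported schema_version '%s' (this build reads %s)",
                   doc$schema_version, interchangeSchemaVersion),
           call. = FALSE)
    snap <- snapshotFromList(doc, name = name)
  }
  if (schema_check) checkIdentifierSyntax(snap, id_patterns)
  snap
}

refuseForeignFormats <- function(path) {
  ext <- tolower(tools::file_ext(path))
  head <- tryCatch(readChar(path, 256L, useBytes = TRUE),
                   error = function(e) "")
  if (ext %in% c("xml", "sbml", "owl") || grepl("^\\s*<", head))
    stop("SBML/BioPAX input is not supported; convert the model to the ",
         "interchange JSON (schema_version ", interchangeSchemaVersion,
         ", top-level arrays genes/metabolites/reactions/pathways) or the ",
         "TSV bundle and retry", call. = FALSE)
  invisible(TRUE)
}

snapshotFromList <- function(doc, name = NULL) {
  nm <- name %||% (doc$name %||% "snapshot")
  gtab <- if (length(doc$genes)) do.call(rbind, lapply(doc$genes, function(g)
    data.frame(local_id = optChr(g$local_id), gene_id = optChr(g$gene_id),
               stringsAsFactors = FALSE)))
  mtab <- if (length(doc$metabolites)) {
    rows <- lapply(doc$metabolites, function(m) {
      ids <- m$ids %||% list()
      df <- data.frame(
        local_id = optChr(m$local_id), formula = optChr(m$formula),
        charge = optInt(m$charge), compartment = optChr(m$compartment),
        kegg_compound = optChr(ids$kegg_compound),
        kegg_glycan = optChr(ids$kegg_glycan), chebi = optChr(ids$chebi),
        pubchem_compound = optChr(ids$pubchem_compound),
        cas = optChr(ids$cas),
        is_generic = optLgl(m$is_generic, FALSE),
        is_protein = optLgl(m$is_protein, FALSE),
        stringsAsFactors = FALSE)
      df$names <- list(as.character(unlist(m$names)))
      df$instance_ids <- list(as.character(unlist(m$instance_ids)))
      df
    })
    do.call(rbind, rows)
  }
  rtab <- if (length(doc$reactions)) {
    rows <- lapply(doc$reactions, function(r) {
      side <- function(s) {
        if (length(s) == 0)
          stop("reaction ", optChr(r$local_id), ": empty side", call. = FALSE)
        v <- vapply(s, function(p) as.numeric(p$coefficient %||% 1),
                    numeric(1))
        names(v) <- vapply(s, function(p) optChr(p$metabolite), character(1))
        v
      }
      df <- data.frame(local_id = optChr(r$local_id),
                       reversible = optLgl(r$reversible, NA),
                       is_set_reaction = optLgl(r$is_set_reaction, FALSE),
                       expansion_flagged = optLgl(r$expansion_flagged, FALSE),
                       stringsAsFactors = FALSE)
      df$side_a <- list(side(r$side_a))
      df$side_b <- list(side(r$side_b))
      df$genes <- list(as.character(unlist(r$genes)))
      df$ecs <- list(as.character(unlist(r$ecs)))
      df$pathways <- list(as.character(unlist(r$pathways)))
      df
    })
    do.call(rbind, rows)
  }
  ptab <- if (length(doc$pathways)) do.call(rbind, lapply(doc$pathways,
    function(p) data.frame(local_id = optChr(p$local_id),
                           name = optChr(p$name) %||% NA_character_,
                           category = optChr(p$category),
                           stringsAsFactors = FALSE)))
  if (!is.null(ptab) && anyNA(ptab$name)) ptab$name <- ifelse(
    is.na(ptab$name), ptab$local_id, ptab$name)
  tryCatch(
    databaseSnapshot(nm, genes = gtab, metabolites = mtab, reactions = rtab,
                     pathways = ptab),
    error = function(e) stop("snapshot '", nm, "' failed validation: ",
                             conditionMessage(e), call. = FALSE))
}

checkIdentifierSyntax <- function(snap, id_patterns) {
  bad <- character(0)
  m <- metabolites(snap)
  for (ns in metNamespaces()) {
    v <- m[[ns]]
    w <- !is.na(v) & !grepl(id_patterns[[ns]], v)
    if (any(w)) bad <- c(bad, sprintf("%s '%s' (metabolite %s)",
                                      ns, v[w], m$local_id[w]))
  }
  g <- genes(snap)
  wg <- !is.na(g$gene_id) & !grepl(id_patterns[["gene"]], g$gene_id)
  if (any(wg)) bad <- c(bad, sprintf("gene_id '%s' (gene %s)",
                                     g$gene_id[wg], g$local_id[wg]))
  if (length(bad))
    stop("identifier syntax violations in snapshot '", snapshotName(snap),
         "': ", paste(bad, collapse = "; "), call. = FALSE)
  invisible(TRUE)
}

# ---- writing ----------------------------------------------------------------

#' Write a snapshot to interchange JSON
#'
#' Output is canonical: records sorted by \code{local_id}, side members by
#' metabolite id, list fields sorted, absent fields omitted. Reading the file
#' back reproduces the snapshot field-for-field, and identical snapshots
#' always produce byte-identical files.
#'
#' @param snap A [DatabaseSnapshot].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeSnapshot <- function(snap, path) {
  doc <- snapshotToList(snap)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

snapshotToList <- function(snap) {
  m <- metabolites(snap); r <- reactions(snap)
  g <- genes(snap); p <- pathways(snap)
  ord <- function(df) if (nrow(df)) df[order(df$local_id), , drop = FALSE] else df
  g <- ord(g); m <- ord(m); r <- ord(r); p <- ord(p)
  drop_na <- function(x) x[!vapply(x, function(v)
    is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
  side_out <- function(s) lapply(seq_along(s), function(i)
    list(metabolite = names(s)[i], coefficient = unname(s[i])))
  list(
    schema_version = interchangeSchemaVersion,
    name = snapshotName(snap),
    genes = lapply(seq_len(nrow(g)), function(i) drop_na(list(
      local_id = g$local_id[i], gene_id = g$gene_id[i]))),
    metabolites = lapply(seq_len(nrow(m)), function(i) {
      ids <- drop_na(list(
        kegg_compound = m$kegg_compound[i], kegg_glycan = m$kegg_glycan[i],
        chebi = m$chebi[i], pubchem_compound = m$pubchem_compound[i],
        cas = m$cas[i]))
      out <- drop_na(list(
        local_id = m$local_id[i], names = as.list(m$names[[i]]),
        formula = m$formula[i], charge = m$charge[i],
        compartment = m$compartment[i]))
      out$ids <- ids
      out$is_generic <- m$is_generic[i]
      out$is_protein <- m$is_protein[i]
      out$instance_ids <- as.list(sort(m$instance_ids[[i]]))
      out
    }),
    reactions = lapply(seq_len(nrow(r)), function(i) {
      out <- drop_na(list(local_id = r$local_id[i],
                          reversible = r$reversible[i]))
      out$side_a <- side_out(r$side_a[[i]])
      out$side_b <- side_out(r$side_b[[i]])
      out$genes <- as.list(sort(r$genes[[i]]))
      out$ecs <- as.list(sort(r$ecs[[i]]))
      out$pathways <- as.list(sort(r$pathways[[i]]))
      out$is_set_reaction <- r$is_set_reaction[i]
      out$expansion_flagged <- r$expansion_flagged[i]
      out
    }),
    pathways = lapply(seq_len(nrow(p)), function(i) drop_na(list(
      local_id = p$local_id[i], name = p$name[i], category = p$category[i])))
  )
}

# ---- TSV bundle -------------------------------------------------------------

readSnapshotTSV <- function(dir, name) {
  rd <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) return(NULL)
    utils::read.delim(fp, stringsAsFactors = FALSE, colClasses = "character",
                      na.strings = "", quote = "")
  }
  g <- rd("genes.tsv")
  m <- rd("metabolites.tsv")
  r <- rd("reactions.tsv")
  p <- rd("pathways.tsv")
  if (!is.null(m)) {
    m$names <- lapply(m$names, splitList)
    if ("instance_ids" %in% names(m))
      m$instance_ids <- lapply(m$instance_ids, function(x)
        if (is.na(x)) character(0) else splitList(x))
    for (col in c("is_generic", "is_protein"))
      if (col %in% names(m)) m[[col]] <- toupper(m[[col]]) %in% c("TRUE", "1")
    if ("charge" %in% names(m)) m$charge <- as.integer(m$charge)
  }
  if (!is.null(r)) {
    parse_side <- function(x, rid) {
      if (is.na(x) || !nzchar(x))
        stop("reaction ", rid, ": empty side in reactions.tsv", call. = FALSE)
      parts <- strsplit(splitList(x), ":", fixed = TRUE)
      v <- vapply(parts, function(p)
        if (length(p) > 1) as.numeric(p[2]) else 1, numeric(1))
      names(v) <- vapply(parts, `[`, character(1), 1L)
      v
    }
    r$side_a <- mapply(parse_side, r$side_a, r$local_id, SIMPLIFY = FALSE)
    r$side_b <- mapply(parse_side, r$side_b, r$local_id, SIMPLIFY = FALSE)
    for (col in c("genes", "ecs", "pathways"))
      if (col %in% names(r)) r[[col]] <- lapply(r[[col]], function(x)
        if (is.na(x)) character(0) else splitList(x))
    for (col in c("is_set_reaction", "expansion_flagged"))
      if (col %in% names(r)) r[[col]] <- toupper(r[[col]]) %in% c("TRUE", "1")
    if ("reversible" %in% names(r))
      r$reversible <- as.logical(toupper(r$reversible))
  }
  databaseSnapshot(name, genes = g, metabolites = m, reactions = r,
                   pathways = p)
}

# ---- update tables ----------------------------------------------------------

#' Construct identifier update tables
#'
#' @param transferred Named list: namespace -> named character vector
#'   mapping old identifier to current identifier. Maps must be
#'   pre-flattened (a target may not itself be a key).
#' @param obsolete Named list: namespace -> character vector of identifiers
#'   retired without replacement.
#' @return An [UpdateTables] object.
#' @examples
#' updateTables(transferred = list(gene = c("123" = "456")),
#'              obsolete = list(kegg_compound = "C99999"))
#' @export
updateTables <- function(transferred = list(), obsolete = list()) {
  transferred <- lapply(transferred, function(x) {
    v <- as.character(x); names(v) <- names(x); v
  })
  obsolete <- lapply(obsolete, as.character)
  new("UpdateTables", transferred = transferred, obsolete = obsolete)
}

#' Read update tables from two-column TSV files
#'
#' Each namespace is one TSV with header \code{old<TAB>new}; an empty
#' \code{new} cell marks the identifier obsolete.
#'
#' @param paths Named character vector namespace -> file path, or a
#'   directory containing files named \code{<namespace>.tsv}.
#' @return An [UpdateTables] object.
#' @export
readUpdateTables <- function(paths) {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
    paths <- stats::setNames(files, sub("\\.tsv$", "", basename(files)))
  }
  transferred <- list()
  obsolete <- list()
  for (ns in names(paths)) {
    tab <- utils::read.delim(paths[[ns]], stringsAsFactors = FALSE,
                             colClasses = "character", na.strings = "",
                             quote = "")
    if (!all(c("old", "new") %in% names(tab)))
      stop("update table ", paths[[ns]],
           " must have columns 'old' and 'new'", call. = FALSE)
    is_ob <- is.na(tab$new)
    tr <- tab$new[!is_ob]
    names(tr) <- tab$old[!is_ob]
    transferred[[ns]] <- tr
    obsolete[[ns]] <- tab$old[is_ob]
  }
  updateTables(transferred, obsolete)
}

#' Write update tables to two-column TSV files
#'
#' @param tables An [UpdateTables] object.
#' @param dir Output directory; one \code{<namespace>.tsv} per namespace.
#' @return \code{dir}, invisibly.
#' @export
writeUpdateTables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spaces <- sort(union(names(tables@transferred), names(tables@obsolete)))
  for (ns in spaces) {
    tr <- tables@transferred[[ns]] %||% character(0)
    ob <- tables@obsolete[[ns]] %||% character(0)
    df <- rbind(
      data.frame(old = names(tr), new = unname(tr),
                 stringsAsFactors = FALSE),
      data.frame(old = ob, new = rep("", length(ob)),
                 stringsAsFactors = FALSE))
    df <- df[order(df$old), , drop = FALSE]
    utils::write.table(df, file.path(dir, paste0(ns, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
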