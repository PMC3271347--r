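#' @include expand.R
NULL

#' Configure the entity-resolution cascade
#'
#' @param ignore_metabolites Currency species removed from both reaction
#'   sides before reaction identity is evaluated ("relaxed" matching). The
#'   default — electrons, protons and water — reflects that reactions are
#'   frequently unbalanced with respect to exactly these species. Entries
#'   are labels from the built-in descriptor table (\code{"e-"},
#'   \code{"H+"}, \code{"H2O"}), primary compound identifiers
#'   (\code{"C00001"}), or metabolite names; use \code{character(0)} for
#'   strict matching. A TCA-style single-pathway comparison conventionally
#'   uses \code{"H+"} only.
#' @param h_tolerant_formula When \code{TRUE}, formula comparison in the
#'   name route disregards the hydrogen count, absorbing protonation-state
#'   differences between databases. Default \code{FALSE}.
#' @param override_pairs data.frame with columns \code{a}, \code{b} of
#'   metabolite descriptors (\code{"namespace:identifier"}, e.g.
#'   \code{"kegg_compound:C15972"}, or \code{"snapshot:local_id"}) that are
#'   forced to match regardless of the cascade — the mechanism for
#'   hand-curated equivalences such as enzyme-bound/unbound forms
#'   (lipoamide-E vs lipoamide).
#' @param generic_specific_guard Never match a generic class metabolite
#'   ("an alcohol") with a specific one ("ethanol"). Default \code{TRUE}.
#' @param name_requires_formula A shared name only counts as a match when
#'   both records carry a chemical formula and the formulas agree; a record
#'   with no formula cannot match by name. Default \code{TRUE}.
#' @return A [MatchConfig] object.
#' @examples
#' strict <- matchConfig(ignore_metabolites = character(0))
#' relaxed <- matchConfig()
#' tca <- matchConfig(ignore_metabolites = "H+",
#'   override_pairs = data.frame(a = "kegg_compound:C15972",
#'                               b = "kegg_compound:C00248"))
#' @export
matchConfig <- function(ignore_metabolites = c("e-", "H+", "H2O"),
                        h_tolerant_formula = FALSE, override_pairs = NULL,
                        generic_specific_guard = TRUE,
                        name_requires_formula = TRUE) {
  if (is.null(override_pairs))
    override_pairs <- data.frame(a = character(0), b = character(0),
                                 stringsAsFactors = FALSE)
  stopifnot(all(c("a", "b") %in% names(override_pairs)))
  override_pairs <- data.frame(a = as.character(override_pairs$a),
                               b = as.character(override_pairs$b),
                               stringsAsFactors = FALSE)
  new("MatchConfig", ignore_metabolites = as.character(ignore_metabolites),
      h_tolerant_formula = h_tolerant_formula,
      override_pairs = override_pairs,
      generic_specific_guard = generic_specific_guard,
      name_requires_formula = name_requires_formula)
}

#' Read a MatchConfig from a YAML/JSON block
#'
#' @param x A file path or a pre-parsed list (as from [yaml::read_yaml()]).
#'   Recognized fields mirror the arguments of [matchConfig()];
#'   \code{override_pairs} may also name a two-column TSV file
#'   (\code{a<TAB>b} descriptors).
#' @return A [MatchConfig].
#' @export
matchConfigFromList <- function(x) {
  if (is.character(x) && length(x) == 1) x <- yaml::read_yaml(x)
  ov <- x$override_pairs
  if (is.character(ov) && length(ov) == 1 && file.exists(ov))
    ov <- utils::read.delim(ov, stringsAsFactors = FALSE,
                            colClasses = "character", quote = "")
  if (is.list(ov) && !is.data.frame(ov) && length(ov))
    ov <- data.frame(a = vapply(ov, `[[`, character(1), 1),
                     b = vapply(ov, `[[`, character(1), 2),
                     stringsAsFactors = FALSE)
  matchConfig(
    ignore_metabolites = unlist(x$ignore_metabolites) %||%
      c("e-", "H+", "H2O"),
    h_tolerant_formula = x$h_tolerant_formula %||% FALSE,
    override_pairs = if (is.data.frame(ov)) ov else NULL,
    generic_specific_guard = x$generic_specific_guard %||% TRUE,
    name_requires_formula = x$name_requires_formula %||% TRUE)
}

# descriptor table for the built-in currency species
ignoreSpeciesTable <- function() {
  data.frame(
    label = c("e-", "H+", "H2O"),
    kegg_compound = c("C05359", "C00080", "C00001"),
    names = I(list(c("e-", "electron"), c("H+", "proton", "hydron"),
                   c("H2O", "water"))),
    stringsAsFactors = FALSE
  )
}

# resolve cfg@ignore_metabolites to (kegg ids, normalized names)
resolveIgnoreDescriptors <- function(cfg) {
  tab <- ignoreSpeciesTable()
  keggs <- character(0)
  nms <- character(0)
  for (lab in cfg@ignore_metabolites) {
    hit <- match(lab, tab$label)
    if (!is.na(hit)) {
      keggs <- c(keggs, tab$kegg_compound[hit])
      nms <- c(nms, normalizeName(tab$names[[hit]]))
    } else if (grepl("^[A-Z][0-9]{5}$", lab)) {
      keggs <- c(keggs, lab)
    } else {
      nms <- c(nms, normalizeName(lab))
    }
  }
  list(kegg = unique(keggs), names = unique(nms))
}
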