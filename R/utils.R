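#' Round a ratio to a whole percentage, halves up
#'
#' Overlap statistics are conventionally printed as whole percentages of the
#' union. This helper uses round-half-up (so 16.5 prints as 17), the
#' convention under which published consensus tables are internally
#' consistent, rather than R's banker's rounding.
#'
#' @param count Numerator count (numeric, may be a vector).
#' @param total Denominator count (union size).
#' @return Integer percentage(s).
#' @examples
#' percentRound(5, 30)    # 17
#' percentRound(510, 3858) # 13
#' @export
percentRound <- function(count, total) {
  stopifnot(all(total > 0))
  as.integer(floor(100 * count / total + 0.5))
}

#' Parse a Hill-style chemical formula into element counts
#'
#' @param formula A formula string such as \code{"C6H12O6"}.
#' @return Named integer vector of element counts, sorted by element symbol;
#'   \code{NULL} for \code{NA} input.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(formula) {
  if (is.null(formula) || length(formula) == 0 || is.na(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)
  if (m[[1]][1] == -1) return(stats::setNames(integer(0), character(0)))
  parts <- regmatches(formula, m)[[1]]
  parts <- parts[nzchar(parts)]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(ct == "", 1L, suppressWarnings(as.integer(ct)))
  out <- tapply(ct, el, sum)
  res <- as.integer(out)
  names(res) <- names(out)
  res[order(names(res))]
}

#' Compare two chemical formulas for equality
#'
#' Formulas are compared on parsed element counts so \code{"C2H6O"} and
#' \code{"H6C2O"} agree. With \code{h_tolerant = TRUE} the hydrogen count is
#' disregarded entirely, which absorbs differences in recorded protonation
#' state between databases.
#'
#' @param a,b Formula strings (may be \code{NA}).
#' @param h_tolerant Ignore the H count?
#' @return \code{TRUE}/\code{FALSE}; \code{FALSE} when either side is absent.
#' @export
formulaEqual <- function(a, b, h_tolerant = FALSE) {
  pa <- parseFormula(a)
  pb <- parseFormula(b)
  if (is.null(pa) || is.null(pb)) return(FALSE)
  if (h_tolerant) {
    pa <- pa[names(pa) != "H"]
    pb <- pb[names(pb) != "H"]
  }
  identical(pa, pb)
}

# entity key: globally unique handle for one record of one snapshot
entityKey <- function(snapshot, local_id) paste0(snapshot, "::", local_id)

splitKey <- function(key) {
  parts <- strsplit(key, "::", fixed = TRUE)
  data.frame(
    snapshot = vapply(parts, `[`, character(1), 1L),
    local_id = vapply(parts, function(p) paste(p[-1], collapse = "::"),
                      character(1)),
    stringsAsFactors = FALSE
  )
}

# pipe-joined canonical set rendering used by signatures and TSV list cells
joinSet <- function(x) paste(sort(unique(x)), collapse = "|")

splitList <- function(x) {
  if (is.na(x) || x == "") character(0) else strsplit(x, "|", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar-or-NA coercion for optional fields coming out of JSON
optChr <- function(x) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) NA_character_
  else as.character(x)[1]
}

optInt <- function(x) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) NA_integer_
  else as.integer(x)[1]
}

optLgl <- function(x, default = NA) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) default
  else as.logical(x)[1]
}
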