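#' @include AllClasses.R
NULL

#' Accessors for PathCompare classes
#'
#' Slot accessors for [DatabaseSnapshot], [MatchPartition],
#' [ComparisonResult], [GroundTruth] and [TruthLedger] objects. Use these
#' rather than \code{@} access.
#'
#' @param x The object.
#' @return The corresponding component (a character scalar or a
#'   \code{data.frame}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("snapshotName", function(x) standardGeneric("snapshotName"))

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("pathways", function(x) standardGeneric("pathways"))

#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))

#' @rdname accessors
#' @export
setGeneric("excludedEntities", function(x) standardGeneric("excludedEntities"))

#' @rdname accessors
#' @export
setGeneric("truthEntries", function(x) standardGeneric("truthEntries"))

#' @rdname accessors
#' @export
setGeneric("truthSnapshot", function(x) standardGeneric("truthSnapshot"))

#' Summary counts of a comparison
#'
#' @param x A [ComparisonResult].
#' @return \code{unionSize}: integer; \code{consensusPct}/\code{majorityPct}:
#'   integer whole percentages; \code{occurrenceHistogram}: named integer
#'   vector over k = 1..N; \code{uniqueCounts}: named integer vector per
#'   snapshot.
#' @name comparison-accessors
NULL

#' @rdname comparison-accessors
#' @export
setGeneric("unionSize", function(x) standardGeneric("unionSize"))

#' @rdname comparison-accessors
#' @export
setGeneric("consensusPct", function(x) standardGeneric("consensusPct"))

#' @rdname comparison-accessors
#' @export
setGeneric("majorityPct", function(x) standardGeneric("majorityPct"))

#' @rdname comparison-accessors
#' @export
setGeneric("occurrenceHistogram",
           function(x) standardGeneric("occurrenceHistogram"))

#' @rdname comparison-accessors
#' @export
setGeneric("uniqueCounts", function(x) standardGeneric("uniqueCounts"))
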