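#' @include updates.R
NULL

#' Instantiate reactions written over generic/set metabolites
#'
#' Some databases write reactions over classes of metabolites ("an alcohol
#' -> an aldehyde") or over explicit sets. In \code{"first_member"} mode each
#' such reaction is instantiated once by substituting the first listed
#' instance of every class, pairing the k-th class on the left-hand side
#' with the k-th class on the right-hand side. In \code{"all_members"} mode
#' one instantiated reaction is emitted per member index (the i-th members
#' of all paired classes together), up to the shortest instance list. In
#' \code{"none"} mode the snapshot is returned unchanged.
#'
#' Classes without recorded instances are left in place and the reaction is
#' flagged (\code{expansion_flagged}); likewise a reaction whose two sides
#' carry unequal numbers of instantiable classes, where positional pairing
#' is ill-defined, is left unexpanded and flagged rather than guessed at.
#' Instance metabolites remain ordinary records of the snapshot either way,
#' so metabolite-level comparisons always see them as match candidates.
#'
#' @param snap A [DatabaseSnapshot].
#' @param mode One of \code{"first_member"}, \code{"all_members"},
#'   \code{"none"}.
#' @return The snapshot with set reactions instantiated (non-generic
#'   reactions are never altered).
#' @export
expandGenericReactions <- function(snap,
                                   mode = c("first_member", "all_members",
                                            "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(snap)
  m <- metabolites(snap)
  inst_of <- stats::setNames(m$instance_ids, m$local_id)
  generic <- stats::setNames(m$is_generic, m$local_id)
  r <- reactions(snap)
  if (nrow(r) == 0) return(snap)
  out_rows <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    row <- r[i, , drop = FALSE]
    sa <- row$side_a[[1]]; sb <- row$side_b[[1]]
    class_a <- names(sa)[generic[names(sa)] %in% TRUE]
    class_b <- names(sb)[generic[names(sb)] %in% TRUE]
    if (length(class_a) + length(class_b) == 0) {
      out_rows[[i]] <- row
      next
    }
    exp_a <- class_a[vapply(inst_of[class_a], length, integer(1)) > 0]
    exp_b <- class_b[vapply(inst_of[class_b], length, integer(1)) > 0]
    bare <- c(setdiff(class_a, exp_a), setdiff(class_b, exp_b))
    if (length(exp_a) != length(exp_b)) {
      row$expansion_flagged <- TRUE   # positional pairing ill-defined
      out_rows[[i]] <- row
      next
    }
    if (length(exp_a) == 0) {
      row$expansion_flagged <- TRUE   # classes with no instances at all
      out_rows[[i]] <- row
      next
    }
    n_inst <- if (mode == "first_member") 1L else
      min(vapply(inst_of[c(exp_a, exp_b)], length, integer(1)))
    inst_rows <- lapply(seq_len(n_inst), function(k) {
      subst <- function(s, cls) {
        for (cid in cls) {
          member <- inst_of[[cid]][k]
          coef <- s[[cid]]
          s <- s[names(s) != cid]
          # merge if the member already participates on this side
          if (member %in% names(s)) s[[member]] <- s[[member]] + coef
          else s[[member]] <- coef
        }
        s[order(names(s))]
      }
      nr <- row
      nr$local_id <- if (mode == "first_member") row$local_id else
        paste0(row$local_id, "__", k)
      nr$side_a <- list(subst(sa, exp_a))
      nr$side_b <- list(subst(sb, exp_b))
      nr$is_set_reaction <- length(bare) > 0
      nr$expansion_flagged <- length(bare) > 0
      nr
    })
    out_rows[[i]] <- do.call(rbind, inst_rows)
  }
  r2 <- do.call(rbind, out_rows)
  rownames(r2) <- NULL
  out <- new("DatabaseSnapshot", name = snapshotName(snap),
             genes = genes(snap), metabolites = m, reactions = r2,
             pathways = pathways(snap))
  validObject(out)
  out
}
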