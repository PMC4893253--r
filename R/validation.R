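#' Do a protease and a substrate come from the same organism?
#'
#' Species sameness is equality of taxon identifiers (the worked examples
#' compare at species level, e.g. `NCBI:9606`); lineages are retained in
#' the taxon table but not consulted here.
#'
#' @param kb A `cleavage_kb`.
#' @param protease_acc,substrate_acc Protein accessions.
#' @return List with `match` (logical) and `taxon_id` (the shared id when
#'   `match` is `TRUE`, otherwise `NA`).
#' @export
taxon_match <- function(kb, protease_acc, substrate_acc) {
  p <- kb_protein(kb, protease_acc)
  s <- kb_protein(kb, substrate_acc)
  ok <- !is.na(p$taxon_id) && !is.na(s$taxon_id) && p$taxon_id == s$taxon_id
  list(match = ok, taxon_id = if (ok) p$taxon_id else NA_character_)
}

#' Shared cellular locations of a protease and a substrate
#'
#' Intersection of the two proteins' GO cellular-component annotation
#' sets.  By default leaf annotations are intersected directly, as in the
#' worked co-location examples; `propagate = TRUE` closes both sets over
#' `is_a` ancestors (restricted to cellular_component terms) before
#' intersecting.
#'
#' @inheritParams taxon_match
#' @param propagate Close annotation sets over is_a ancestors first
#'   (default `FALSE`).
#' @return Sorted character vector of shared GO cellular-component ids.
#' @export
shared_locations <- function(kb, protease_acc, substrate_acc, propagate = FALSE) {
  p <- kb_protein(kb, protease_acc)
  s <- kb_protein(kb, substrate_acc)
  lp <- p$locations
  ls <- s$locations
  if (propagate) {
    close_up <- function(terms) {
      anc <- unique(unlist(lapply(terms, go_ancestors, go = kb$go), use.names = FALSE))
      anc <- anc[go_namespace(kb$go, anc) == "cellular_component"]
      union(terms, anc)
    }
    lp <- close_up(lp)
    ls <- close_up(ls)
  }
  sort(intersect(lp, ls))
}

#' Corroborate a proteolysis event by taxon and co-location
#'
#' An event is corroborated when the protease and substrate share their
#' taxon and at least one cellular location.  The verdict is reported
#' alongside the event — it never deletes events and never alters their
#' knowledge status or confidence; results corroborated by context may
#' simply be interpreted with more confidence.
#'
#' @param kb A `cleavage_kb`.
#' @param event A one-row event data.frame.
#' @return The event with columns `taxon_match` (logical),
#'   `shared_locations` (semicolon-joined GO ids) and `verdict`
#'   (`corroborated`, `uncorroborated` or `unevaluable`) appended.
#' @export
validate_event <- function(kb, event) {
  stopifnot(nrow(event) == 1L)
  res <- tryCatch({
    tm <- taxon_match(kb, event$protease_accession, event$substrate_accession)
    sl <- shared_locations(kb, event$protease_accession, event$substrate_accession)
    p <- kb_protein(kb, event$protease_accession)
    s <- kb_protein(kb, event$substrate_accession)
    if (!length(p$locations) || !length(s$locations))
      warnf("event %s: %s has no cellular-component annotation; co-location unassessable",
            event$event_id,
            if (!length(p$locations)) event$protease_accession else event$substrate_accession)
    list(tm = tm$match, sl = sl,
         verdict = if (tm$match && length(sl)) "corroborated" else "uncorroborated")
  }, error = function(e) list(tm = NA, sl = character(), verdict = "unevaluable"))
  event$taxon_match <- res$tm
  event$shared_locations <- paste(res$sl, collapse = ";")
  event$verdict <- res$verdict
  event
}

#' @rdname validate_event
#' @param events An event data.frame (any number of rows).
#' @export
validate_events <- function(kb, events) {
  if (!nrow(events)) {
    events$taxon_match <- logical()
    events$shared_locations <- character()
    events$verdict <- character()
    return(events)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(events)), function(i)
    validate_event(kb, events[i, , drop = FALSE])))
  rownames(out) <- NULL
  out
}
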