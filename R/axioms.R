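#' Export the knowledge base and event ledger as axiom patterns
#'
#' Renders the knowledge base plus a set of proteolysis events as one
#' axiom per line in a Manchester-like surface syntax, instantiating the
#' recurring patterns the knowledge model is built on: protein annotation
#' axioms (`'has function'`, `'has location'`, `'participates in'`,
#' `'only in taxon'`), cleavage-site parthood (`'part of'` some protein),
#' the protease equivalence definition, and per-event output-of axioms
#' carrying the knowledge-status literal (`'Observed status'` /
#' `'Predicted status'`) and, for predictions, a confidence-level
#' conjunct.  Ordering is deterministic (entity id, then axiom kind), so
#' re-export of the same knowledge base is byte-identical, and distinct
#' events always yield distinct axiom lines.
#'
#' @param kb A `cleavage_kb`.
#' @param events Event data.frame; defaults to the knowledge base's own
#'   ledger.
#' @param path Output file path.
#' @param format `"text"` for the axiom lines, `"json"` for a structural
#'   mirror with one object per axiom (`subject`, `pattern`, `fillers`).
#' @return `path`, invisibly.
#' @export
export_axioms <- function(kb, events = kb$events, path,
                          format = c("text", "json")) {
  format <- match.arg(format)
  ax <- build_axioms(kb, events)
  if (format == "text") {
    writeLines(vapply(ax, `[[`, "", "line"), path)
  } else {
    jsonlite::write_json(
      lapply(ax, function(a) list(subject = a$subject, pattern = a$pattern,
                                  fillers = a$fillers)),
      path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

build_axioms <- function(kb, events) {
  ax <- list()
  add <- function(subject, pattern, fillers, line)
    ax[[length(ax) + 1L]] <<- list(subject = subject, pattern = pattern,
                                   fillers = fillers, line = line)
  anchors <- protease_anchor_terms()
  if (length(kb$proteins) || nrow(events))
    add("Protease", "equivalence", list(anchor = unname(anchors[["protease"]])),
        sprintf("Protease EquivalentTo Protein and ('has function' some %s)",
                anchors[["protease"]]))
  for (acc in names(kb$proteins)) {
    p <- kb$proteins[[acc]]
    for (t in p$functions)
      add(acc, "has_function", list(term = t),
          sprintf("%s SubClassOf 'has function' some %s", acc, t))
    for (t in p$locations)
      add(acc, "has_location", list(term = t),
          sprintf("%s SubClassOf 'has location' some %s", acc, t))
    for (t in p$processes)
      add(acc, "participates_in", list(term = t),
          sprintf("%s SubClassOf 'participates in' some %s", acc, t))
    if (!is.na(p$taxon_id))
      add(acc, "only_in_taxon", list(taxon = p$taxon_id),
          sprintf("%s SubClassOf 'only in taxon' some %s", acc, p$taxon_id))
  }
  cs <- kb$cleavage_sites
  if (nrow(cs)) for (i in seq_len(nrow(cs))) {
    cs_id <- sprintf("CS:%s:%d", cs$substrate_accession[i], cs$p1_position[i])
    add(cs_id, "part_of", list(protein = cs$substrate_accession[i]),
        sprintf("%s SubClassOf 'part of' some %s", cs_id,
                cs$substrate_accession[i]))
  }
  if (nrow(events)) {
    events <- events[order(events$event_id), , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      status <- if (e$knowledge_status == "observed") "Observed status"
                else "Predicted status"
      subj <- sprintf("PEP:%s:%s", e$peptide_id, e$terminus)
      conj <- sprintf(paste0("Proteolysis and ('has input' some %s) and",
                             " ('has input' some %s) and (hasP1 value %d)",
                             " and (hasKnowledgeStatus some '%s')"),
                      e$protease_accession, e$substrate_accession,
                      e$p1_position, status)
      if (e$knowledge_status == "predicted")
        conj <- sprintf("%s and (hasConfidenceLevelStatus some '%s confidence')",
                        conj, e$confidence)
      add(subj, "output_of",
          list(protease = e$protease_accession,
               substrate = e$substrate_accession,
               p1_position = e$p1_position, status = status,
               confidence = if (e$knowledge_status == "predicted")
                 e$confidence else NULL,
               rescue = e$rescue),
          sprintf("%s SubClassOf 'output of' some (%s)%s", subj, conj,
                  if (isTRUE(e$rescue)) " [rescue]" else ""))
    }
  }
  ax
}
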