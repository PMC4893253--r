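#' Construct a protein record
#'
#' The unit both substrates and proteases are drawn from: an accession, a
#' sequence over the 20-letter alphabet, and annotation facets (GO
#' molecular functions, biological processes, cellular locations), a taxon
#' and optionally a gene.
#'
#' @param accession Primary identifier (opaque CURIE-like string, e.g.
#'   `"PR:P02768"`); prefixes are preserved verbatim.
#' @param sequence Amino-acid sequence (20 standard one-letter codes).
#' @param label Human-readable name.
#' @param alt_ids Alternative identifiers (e.g. the UniProt entry name).
#' @param taxon_id Taxon identifier (e.g. `"NCBI:9606"`) or `NA`.
#' @param gene_id Gene identifier or `NA`.
#' @param is_isoform Whether the record is an isoform of a canonical entry.
#' @param functions,processes,locations Character vectors of GO term ids in
#'   the molecular_function, biological_process and cellular_component
#'   namespaces respectively.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(accession, sequence, label = accession,
                           alt_ids = character(), taxon_id = NA_character_,
                           gene_id = NA_character_, is_isoform = FALSE,
                           functions = character(), processes = character(),
                           locations = character()) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) abort("protein %s: empty sequence", accession)
  bad <- first_illegal_residue(sequence)
  if (bad > 0L)
    abort("protein %s: illegal residue '%s' at position %d",
          accession, substr(sequence, bad, bad), bad)
  structure(list(accession = accession, alt_ids = as.character(alt_ids),
                 label = label, sequence = sequence,
                 taxon_id = as.character(taxon_id)[1],
                 gene_id = as.character(gene_id)[1],
                 is_isoform = isTRUE(is_isoform),
                 functions = sort(unique(as.character(functions))),
                 processes = sort(unique(as.character(processes))),
                 locations = sort(unique(as.character(locations)))),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein_record %s (%s), %d aa, taxon %s\n  MF: %s\n  BP: %s\n  CC: %s\n",
              x$accession, x$label, nchar(x$sequence), x$taxon_id,
              paste(x$functions, collapse = " "),
              paste(x$processes, collapse = " "),
              paste(x$locations, collapse = " ")))
  invisible(x)
}

taxon_node <- function(taxon_id, name, lineage = character()) {
  structure(list(taxon_id = taxon_id, name = name,
                 lineage = as.character(lineage)),
            class = "taxon_node")
}

empty_cleavage_sites <- function() {
  data.frame(substrate_accession = character(), p1_position = integer(),
             nonprime_length = integer(), site_sequence = character(),
             protease_accession = character(), source = character(),
             stringsAsFactors = FALSE)
}

#' An empty proteolysis-event table
#'
#' Events are plain data.frames with one row per (peptide, terminus,
#' protease) association.  Observed events carry no score or percentile;
#' predicted events carry the log-likelihood score, its percentile rank in
#' the matrix's population score distribution and a banded confidence
#' level.  Rescued events are flagged and paired through
#' `partner_event_id`.
#'
#' @return Zero-row data.frame with the canonical event columns.
#' @export
empty_events <- function() {
  data.frame(event_id = character(), peptide_id = character(),
             terminus = character(), protease_accession = character(),
             substrate_accession = character(), p1_position = integer(),
             knowledge_status = character(), confidence = character(),
             score = numeric(), percentile = numeric(), rescue = logical(),
             partner_event_id = character(), stringsAsFactors = FALSE)
}

event_row <- function(peptide_id, terminus, protease_accession,
                      substrate_accession, p1_position, knowledge_status,
                      confidence = "not-applicable", score = NA_real_,
                      percentile = NA_real_, rescue = FALSE,
                      partner_event_id = NA_character_) {
  data.frame(event_id = paste(peptide_id, terminus, protease_accession,
                              p1_position, if (rescue) "rescue" else "direct",
                              sep = "|"),
             peptide_id = peptide_id, terminus = terminus,
             protease_accession = protease_accession,
             substrate_accession = substrate_accession,
             p1_position = as.integer(p1_position),
             knowledge_status = knowledge_status, confidence = confidence,
             score = score, percentile = percentile, rescue = rescue,
             partner_event_id = partner_event_id, stringsAsFactors = FALSE)
}

#' Assemble and validate a knowledge base
#'
#' Bundles proteins, the GO graph, taxa, observed cleavage-site records,
#' specificity matrices, the amino-acid property table and the exopeptidase
#' catalog into one indexed object.  All cross-references are validated and
#' every violation is reported (not just the first): annotation terms must
#' exist in the graph in the namespace their facet implies, stored
#' cleavage-site sequences must equal the substring recomputed from the
#' substrate sequence, and every protease named by a cleavage-site record
#' or matrix must satisfy the protease definition ([is_protease()]).
#'
#' @param proteins List of [protein_record()] objects.
#' @param go A [go_graph()].
#' @param taxa Named list of taxon nodes (see [read_taxa()]).
#' @param cleavage_sites data.frame of observed protease/cleavage-site
#'   records (see [read_cleavage_sites()]).
#' @param matrices Named list of [specificity_matrix()] objects, keyed by
#'   protease accession.
#' @param aa_properties Amino-acid property table; defaults to the packaged
#'   one.
#' @param exopeptidase_catalog Named character vector mapping protease
#'   accessions to `"aminopeptidase"` or `"carboxypeptidase"`.
#' @return An object of class `cleavage_kb`.
#' @export
knowledge_base <- function(proteins, go, taxa = list(),
                           cleavage_sites = empty_cleavage_sites(),
                           matrices = list(),
                           aa_properties = amino_acid_properties(),
                           exopeptidase_catalog = character()) {
  stopifnot(inherits(go, "go_graph"), is.list(proteins))
  accs <- vapply(proteins, `[[`, "", "accession")
  if (anyDuplicated(accs))
    abort("duplicate protein accession(s): %s",
          paste(unique(accs[duplicated(accs)]), collapse = ", "))
  names(proteins) <- accs
  proteins <- proteins[order(accs)]
  failures <- character()
  note <- function(fmt, ...) failures <<- c(failures, sprintf(fmt, ...))

  ns_of_facet <- c(functions = "molecular_function",
                   processes = "biological_process",
                   locations = "cellular_component")
  for (p in proteins) {
    for (facet in names(ns_of_facet)) {
      for (term in p[[facet]]) {
        if (!go_has_term(go, term)) {
          note("%s: annotation term %s not in GO graph", p$accession, term)
        } else if (go_namespace(go, term) != ns_of_facet[[facet]]) {
          note("%s: term %s has namespace %s, expected %s for facet '%s'",
               p$accession, term, go_namespace(go, term),
               ns_of_facet[[facet]], facet)
        }
      }
    }
    if (!is.na(p$taxon_id) && length(taxa) && !p$taxon_id %in% names(taxa))
      note("%s: taxon %s not in taxon table", p$accession, p$taxon_id)
  }

  cs <- cleavage_sites
  if (nrow(cs)) {
    for (i in seq_len(nrow(cs))) {
      sub <- proteins[[cs$substrate_accession[i]]]
      if (is.null(sub)) {
        note("cleavage site %d: unknown substrate %s", i, cs$substrate_accession[i])
        next
      }
      p1 <- cs$p1_position[i]
      k <- cs$nonprime_length[i]
      len <- nchar(cs$site_sequence[i])
      L <- nchar(sub$sequence)
      if (p1 < 1 || p1 + 1 > L) {
        note("cleavage site %d on %s: P1=%d/P1'=%d outside sequence (1..%d)",
             i, sub$accession, p1, p1 + 1, L)
        next
      }
      from <- p1 - k + 1
      to <- p1 + (len - k)
      if (from < 1 || to > L) {
        note("cleavage site %d on %s: window %d..%d outside sequence (1..%d)",
             i, sub$accession, from, to, L)
        next
      }
      expect <- substr1(sub$sequence, from, to)
      if (expect != cs$site_sequence[i])
        note("cleavage site %d on %s: stored sequence '%s' != substrate substring '%s'",
             i, sub$accession, cs$site_sequence[i], expect)
    }
  }

  anchors <- protease_anchor_terms()
  check_protease <- function(acc, what) {
    p <- proteins[[acc]]
    if (is.null(p)) { note("%s: unknown protein %s", what, acc); return() }
    ok <- tryCatch(is_protease(p, go), error = function(e) { note("%s: %s", what, conditionMessage(e)); FALSE })
    if (!isTRUE(ok))
      note("%s: %s does not satisfy the protease definition (no %s annotation)",
           what, acc, anchors[["protease"]])
  }
  for (acc in unique(cs$protease_accession)) check_protease(acc, "cleavage-site table")
  for (acc in names(matrices)) check_protease(acc, "specificity-matrix table")
  for (acc in names(exopeptidase_catalog)) {
    check_protease(acc, "exopeptidase catalog")
    if (!exopeptidase_catalog[[acc]] %in% c("aminopeptidase", "carboxypeptidase"))
      note("exopeptidase catalog: %s has unknown type '%s'", acc,
           exopeptidase_catalog[[acc]])
  }

  if (!setequal(aa_properties$residue, AA20) || nrow(aa_properties) != 20L)
    note("amino-acid property table must contain the 20 standard residues exactly once")

  if (length(failures))
    abort("knowledge base validation failed:\n  - %s",
          paste(failures, collapse = "\n  - "))

  # canonical order makes downstream output independent of input row order
  if (nrow(cs)) {
    cs <- cs[order(cs$substrate_accession, cs$p1_position,
                   cs$protease_accession), , drop = FALSE]
    rownames(cs) <- NULL
  }
  if (length(matrices)) matrices <- matrices[order(names(matrices))]
  kb <- structure(
    list(proteins = proteins, go = go, taxa = taxa, cleavage_sites = cs,
         matrices = matrices, aa_properties = aa_properties,
         exopeptidase_catalog = exopeptidase_catalog,
         events = empty_events(),
         site_index = build_site_index(cs),
         cache = new.env(parent = emptyenv())),
    class = "cleavage_kb")
  kb
}

# Stage-1 index for observed matching: cleavage-site rows keyed by the two
# residues flanking the scissile bond (P1, P1').
build_site_index <- function(cs) {
  idx <- new.env(parent = emptyenv())
  if (nrow(cs)) {
    p1res <- substr(cs$site_sequence, cs$nonprime_length, cs$nonprime_length)
    p1pres <- substr(cs$site_sequence, cs$nonprime_length + 1L,
                     cs$nonprime_length + 1L)
    keys <- paste0(p1res, p1pres)
    for (i in seq_along(keys))
      assign(keys[i], c(idx[[keys[i]]] %||% integer(), i), envir = idx)
  }
  idx
}

#' @export
print.cleavage_kb <- function(x, ...) {
  cat(sprintf(paste0("cleavage_kb: %d proteins, %d GO terms, %d taxa, ",
                     "%d observed cleavage sites, %d specificity matrices, ",
                     "%d exopeptidases, %d recorded events\n"),
              length(x$proteins), nrow(x$go$terms), length(x$taxa),
              nrow(x$cleavage_sites), length(x$matrices),
              length(x$exopeptidase_catalog), nrow(x$events)))
  invisible(x)
}

kb_protein <- function(kb, accession) {
  p <- kb$proteins[[accession]]
  if (is.null(p)) {
    # fall back to alternative identifiers
    for (q in kb$proteins) if (accession %in% q$alt_ids) return(q)
    abort("unknown protein accession or id: %s", accession)
  }
  p
}

#' Is a protein a protease?
#'
#' A protein is recognised as a protease when one of its molecular-function
#' annotations is peptidase activity (`GO:0008233`) or any `is_a`
#' descendant of it.
#'
#' @param protein A [protein_record()].
#' @param go A [go_graph()] containing the peptidase-activity anchor term.
#' @return `TRUE` or `FALSE`.
#' @export
is_protease <- function(protein, go) {
  anchor <- protease_anchor_terms()[["protease"]]
  if (!go_has_term(go, anchor)) abort("GO graph lacks anchor term %s", anchor)
  unknown <- protein$functions[!vapply(protein$functions, go_has_term, TRUE, go = go)]
  if (length(unknown))
    abort("%s: unknown annotation term(s): %s", protein$accession,
          paste(unknown, collapse = ", "))
  any(vapply(protein$functions, function(t) go_is_a(go, t, anchor), TRUE))
}

#' Classify a protease by catalytic-activity sub-hierarchy
#'
#' Exploits the GO catalytic-activity hierarchy: a class is assigned when
#' an annotation equals or descends from that class's anchor term
#' ([protease_anchor_terms()]).  Aminopeptidase or carboxypeptidase
#' membership implies exopeptidase membership.
#'
#' @inheritParams is_protease
#' @return Character vector drawn from `endopeptidase`, `exopeptidase`,
#'   `aminopeptidase`, `carboxypeptidase` (possibly empty).
#' @export
classify_protease <- function(protein, go) {
  if (!is_protease(protein, go))
    abort("%s is not a protease (no peptidase-activity annotation)",
          protein$accession)
  anchors <- protease_anchor_terms()
  classes <- character()
  for (cls in c("endopeptidase", "exopeptidase", "aminopeptidase", "carboxypeptidase")) {
    if (!go_has_term(go, anchors[[cls]])) next
    if (any(vapply(protein$functions, function(t) go_is_a(go, t, anchors[[cls]]), TRUE)))
      classes <- c(classes, cls)
  }
  if (any(c("aminopeptidase", "carboxypeptidase") %in% classes))
    classes <- union(classes, "exopeptidase")
  sort(unique(classes))
}

#' Record events into the knowledge base's prediction ledger
#'
#' Appends proteolysis events so that they are visible to the competency
#' queries and to the axiom export.  Appending an event with a (peptide,
#' terminus, protease) combination already present is an idempotent no-op
#' with a warning.
#'
#' @param kb A `cleavage_kb`.
#' @param events One or more event rows (data.frame as from
#'   [empty_events()]).
#' @return The updated knowledge base.
#' @export
record_events <- function(kb, events) {
  stopifnot(inherits(kb, "cleavage_kb"))
  if (!nrow(events)) return(kb)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, , drop = FALSE]
    key_new <- paste(ev$peptide_id, ev$terminus, ev$protease_accession)
    key_old <- paste(kb$events$peptide_id, kb$events$terminus,
                     kb$events$protease_accession)
    if (key_new %in% key_old) {
      warnf("duplicate event for (%s) ignored", key_new)
      next
    }
    kb$events <- rbind(kb$events, ev)
  }
  rownames(kb$events) <- NULL
  kb
}

#' @rdname record_events
#' @export
record_observed_event <- function(kb, events) {
  stopifnot(all(events$knowledge_status == "observed"))
  record_events(kb, events)
}

#' CQ: known proteases and their target cleavage sites
#'
#' One row per stored observed cleavage-site record and per recorded
#' predicted event, optionally filtered by knowledge status.
#'
#' @param kb A `cleavage_kb`.
#' @param status_filter Optional: `"observed"` or `"predicted"`.
#' @return data.frame with columns `protease`, `substrate`, `p1_position`,
#'   `site_sequence`, `status`.
#' @export
cq_proteases_and_sites <- function(kb, status_filter = NULL) {
  cs <- kb$cleavage_sites
  obs <- data.frame(protease = cs$protease_accession,
                    substrate = cs$substrate_accession,
                    p1_position = cs$p1_position,
                    site_sequence = cs$site_sequence,
                    status = rep("observed", nrow(cs)),
                    stringsAsFactors = FALSE)
  pred_ev <- kb$events[kb$events$knowledge_status == "predicted", , drop = FALSE]
  pred <- data.frame(protease = pred_ev$protease_accession,
                     substrate = pred_ev$substrate_accession,
                     p1_position = pred_ev$p1_position,
                     site_sequence = rep(NA_character_, nrow(pred_ev)),
                     status = rep("predicted", nrow(pred_ev)),
                     stringsAsFactors = FALSE)
  out <- rbind(obs, pred)
  if (!is.null(status_filter)) {
    stopifnot(status_filter %in% c("observed", "predicted"))
    out <- out[out$status == status_filter, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' CQ: cleavage sites that led to a peptide's production
#'
#' For each terminus of the peptide, reports the observed cleavage-site
#' record(s) matching the reconstructed window, any recorded predicted
#' events, or a `protein-terminus` flag when the peptide starts at residue
#' 1 / ends at the last residue (no scissile bond exists there).
#'
#' @param kb A `cleavage_kb`.
#' @param peptide A peptide input row: list or one-row data.frame with
#'   `peptide_id`, `parent_accession`, `start`, `end`.
#' @param flank Window flank (residues per side), 1..4.
#' @return data.frame with columns `terminus`, `p1_position`,
#'   `site_sequence`, `protease`, `status` (`observed`, `predicted`,
#'   `protein-terminus` or `none`).
#' @export
cq_sites_for_peptide <- function(kb, peptide, flank = 4L) {
  prot <- kb_protein(kb, peptide$parent_accession)
  wins <- reconstruct_termini(prot, peptide, flank = flank)
  out <- list()
  for (term in c("N", "C")) {
    w <- wins[[term]]
    if (w$at_protein_terminus) {
      out[[term]] <- data.frame(terminus = term, p1_position = NA_integer_,
                                site_sequence = NA_character_,
                                protease = NA_character_,
                                status = "protein-terminus",
                                stringsAsFactors = FALSE)
      next
    }
    ev <- match_observed(w, peptide, kb)
    rows <- NULL
    if (nrow(ev)) {
      cs <- kb$cleavage_sites
      hit <- cs$substrate_accession == prot$accession & cs$p1_position == w$p1_position
      seqs <- setNames(cs$site_sequence[hit], cs$protease_accession[hit])
      rows <- data.frame(terminus = term, p1_position = ev$p1_position,
                         site_sequence = unname(seqs[ev$protease_accession]),
                         protease = ev$protease_accession,
                         status = "observed", stringsAsFactors = FALSE)
    }
    pe <- kb$events
    pe <- pe[pe$peptide_id == peptide$peptide_id & pe$terminus == term &
               pe$knowledge_status == "predicted", , drop = FALSE]
    if (nrow(pe))
      rows <- rbind(rows, data.frame(terminus = term,
                                     p1_position = pe$p1_position,
                                     site_sequence = NA_character_,
                                     protease = pe$protease_accession,
                                     status = "predicted",
                                     stringsAsFactors = FALSE))
    if (is.null(rows))
      rows <- data.frame(terminus = term, p1_position = w$p1_position,
                         site_sequence = NA_character_,
                         protease = NA_character_, status = "none",
                         stringsAsFactors = FALSE)
    out[[term]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' CQ: function, species and cellular location of a protein
#'
#' @param kb A `cleavage_kb`.
#' @param accession Protein accession or alternative id.
#' @return List with `functions`, `taxon`, `locations`.
#' @export
cq_context <- function(kb, accession) {
  p <- kb_protein(kb, accession)
  list(functions = p$functions, taxon = p$taxon_id, locations = p$locations)
}

#' CQ: cleavage-site specificity of a protease
#'
#' @param kb A `cleavage_kb`.
#' @param protease_accession Protease accession.
#' @return The stored [specificity_matrix()] or `NULL` when none is
#'   attached (with a warning if the accession does not satisfy the
#'   protease definition).
#' @export
cq_specificity <- function(kb, protease_accession) {
  m <- kb$matrices[[protease_accession]]
  if (is.null(m)) {
    p <- kb$proteins[[protease_accession]]
    if (!is.null(p) && !is_protease(p, kb$go))
      warnf("%s is not a protease; no specificity matrix can be attached",
            protease_accession)
    return(NULL)
  }
  m
}

#' CQ: functions and processes of a protease
#'
#' @param kb A `cleavage_kb`.
#' @param protease_accession Protein accession or alternative id.
#' @return List with `functions` (molecular function term ids) and
#'   `processes` (biological process term ids).
#' @export
cq_functions_processes <- function(kb, protease_accession) {
  p <- kb_protein(kb, protease_accession)
  list(functions = p$functions, processes = p$processes)
}
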