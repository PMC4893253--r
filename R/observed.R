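#' Match a terminus window against observed cleavage-site records
#'
#' Two-stage matching.  Stage 1 (prefilter) looks the window up in the
#' knowledge base's cleavage-site index by the residues flanking the
#' scissile bond and requires the window and record sequences to agree on
#' every position they share (the bond anchors the alignment, so truncated
#' windows match records truncated at the same boundary).  Stage 2
#' (detailed match) requires the record's substrate to be the peptide's
#' parent and its P1 position to equal the window's P1 position; sequence
#' identity alone never creates an event, because repeated motifs on other
#' proteins or at other positions are not evidence for this cleavage.
#' With `sequence_only = TRUE` the positional requirement is dropped
#' (substrate identity and full aligned sequence equality still hold).
#'
#' @param window A `terminus_window` not at a protein terminus.
#' @param peptide Peptide input row (`peptide_id`, `parent_accession`,
#'   `start`, `end`).
#' @param kb A `cleavage_kb`.
#' @param sequence_only Drop the positional identity requirement in the
#'   detailed match (default `FALSE`).
#' @return Event data.frame with `knowledge_status = "observed"`, sorted
#'   by protease accession; empty when nothing matches.
#' @export
match_observed <- function(window, peptide, kb, sequence_only = FALSE) {
  stopifnot(inherits(kb, "cleavage_kb"))
  if (window$at_protein_terminus)
    abort("window at a protein terminus has no scissile bond to match")
  cs <- kb$cleavage_sites
  if (!nrow(cs)) return(empty_events())
  p1res <- substr(window$nonprime, nchar(window$nonprime), nchar(window$nonprime))
  p1pres <- substr(window$prime, 1L, 1L)
  cand <- kb$site_index[[paste0(p1res, p1pres)]]
  if (is.null(cand)) return(empty_events())
  parent <- kb_protein(kb, peptide$parent_accession)
  keep <- integer()
  for (i in cand) {
    if (!site_overlap_equal(window, cs$site_sequence[i], cs$nonprime_length[i]))
      next # prefilter: sequence disagreement on shared positions
    if (cs$substrate_accession[i] != parent$accession) next
    if (!sequence_only && cs$p1_position[i] != window$p1_position) next
    keep <- c(keep, i)
  }
  if (!length(keep)) return(empty_events())
  hits <- cs[keep, , drop = FALSE]
  hits <- hits[order(hits$protease_accession), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(hits)), function(j)
    event_row(peptide_id = peptide$peptide_id, terminus = window$terminus,
              protease_accession = hits$protease_accession[j],
              substrate_accession = hits$substrate_accession[j],
              p1_position = hits$p1_position[j],
              knowledge_status = "observed")))
  rownames(out) <- NULL
  out
}

# Window/record sequence agreement on the positions both cover, anchored at
# the scissile bond.
site_overlap_equal <- function(window, site_sequence, nonprime_length) {
  site_np <- substr1(site_sequence, 1L, nonprime_length)
  site_pr <- substr1(site_sequence, nonprime_length + 1L, nchar(site_sequence))
  k <- min(nchar(window$nonprime), nchar(site_np))
  m <- min(nchar(window$prime), nchar(site_pr))
  if (k + m == 0L) return(FALSE)
  w_np <- substr1(window$nonprime, nchar(window$nonprime) - k + 1L,
                  nchar(window$nonprime))
  s_np <- substr1(site_np, nchar(site_np) - k + 1L, nchar(site_np))
  w_pr <- substr1(window$prime, 1L, m)
  s_pr <- substr1(site_pr, 1L, m)
  identical(w_np, s_np) && identical(w_pr, s_pr)
}
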