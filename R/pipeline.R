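#' Default pipeline configuration
#'
#' Tunable parameters of the prediction pipeline with their defaults:
#' window flank (4 residues per side), match percentile (99), confidence
#' bands, probability-matrix pseudocount (1), matrix usability rule (40
#' cleavages or 10-fold enrichment), maximum exopeptidase trim (2) and
#' the Monte-Carlo cross-check draw count.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
cleave_config <- function(...) {
  cfg <- list(flank = 4L, percentile = 99, pseudocount = 1,
              min_cleavages = 40L, enrichment = 10, max_trim = 2L,
              rescue = TRUE, sequence_only = FALSE,
              bands = confidence_bands(), monte_carlo_draws = 10000L,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    abort("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full protease-prediction pipeline on a peptide table
#'
#' For each peptide: reconstruct the two terminus windows; match each
#' non-terminal window against observed cleavage-site records; only
#' windows that remain unmatched go to matrix-based prediction; termini
#' whose best prediction is below high confidence (or absent) get an
#' exopeptidase-rescue attempt.  All resulting events are annotated with
#' the taxon/co-location corroboration verdict.  The pipeline is fully
#' deterministic — no stage draws random numbers.
#'
#' @param kb A `cleavage_kb`.
#' @param peptides Peptide table as from [read_peptides()].
#' @param config Configuration list from [cleave_config()].
#' @param quiet Suppress per-stage log messages.
#' @return List with `events` (validated event data.frame), `kb` (ledger
#'   updated with all events) and `log` (named stage counts).
#' @export
predict_peptides <- function(kb, peptides, config = cleave_config(),
                             quiet = FALSE) {
  stopifnot(inherits(kb, "cleavage_kb"))
  log <- c(peptides = nrow(peptides), windows = 0L, protein_termini = 0L,
           observed = 0L, predicted = 0L, rescued = 0L, corroborated = 0L)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  all_events <- empty_events()
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides[i, , drop = FALSE]
    parent <- kb_protein(kb, pep$parent_accession)
    wins <- reconstruct_termini(parent, pep, flank = config$flank)
    for (term in c("N", "C")) {
      w <- wins[[term]]
      if (w$at_protein_terminus) {
        log[["protein_termini"]] <- log[["protein_termini"]] + 1L
        next
      }
      log[["windows"]] <- log[["windows"]] + 1L
      obs <- match_observed(w, pep, kb, sequence_only = config$sequence_only)
      if (nrow(obs)) {
        log[["observed"]] <- log[["observed"]] + nrow(obs)
        all_events <- rbind(all_events, obs)
        next # stage ordering: observed termini are never sent to prediction
      }
      pred <- predict_cleavage(w, pep, kb, percentile = config$percentile,
                               pseudocount = config$pseudocount,
                               min_cleavages = config$min_cleavages,
                               enrichment = config$enrichment,
                               bands = config$bands)
      log[["predicted"]] <- log[["predicted"]] + nrow(pred)
      all_events <- rbind(all_events, pred)
      best <- if (nrow(pred)) pred$confidence[1] else "none"
      if (config$rescue && best %in% c("none", "low", "medium")) {
        res <- exopeptidase_rescue(w, pep, kb, max_trim = config$max_trim,
                                   flank = config$flank,
                                   percentile = config$percentile,
                                   pseudocount = config$pseudocount,
                                   min_cleavages = config$min_cleavages,
                                   enrichment = config$enrichment,
                                   bands = config$bands)
        log[["rescued"]] <- log[["rescued"]] + nrow(res)
        all_events <- rbind(all_events, res)
      }
    }
  }
  # drop duplicate (peptide, terminus, protease) rows, keeping the
  # first (highest-ranked) occurrence
  if (nrow(all_events)) {
    key <- paste(all_events$peptide_id, all_events$terminus,
                 all_events$protease_accession)
    all_events <- all_events[!duplicated(key), , drop = FALSE]
    rownames(all_events) <- NULL
  }
  events <- validate_events(kb, all_events)
  log[["corroborated"]] <- sum(events$verdict == "corroborated")
  kb <- suppressWarnings(record_events(kb, all_events))
  say("[input] %d peptides, %d cleavage windows (%d protein termini skipped)",
      log[["peptides"]], log[["windows"]], log[["protein_termini"]])
  say("[observed] %d observed matches", log[["observed"]])
  say("[predicted] %d predictions, %d rescue events", log[["predicted"]],
      log[["rescued"]])
  say("[validated] %d of %d events corroborated by taxon and co-location",
      log[["corroborated"]], nrow(events))
  list(events = events, kb = kb, log = log)
}
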