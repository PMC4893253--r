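#' Construct a specificity matrix
#'
#' Per-position amino-acid occurrence counts across the known cleavages of
#' one protease.  Rows are cleavage-site positions ordered
#' `P<k>..P1, P1'..P<m>'`; columns are residues.  `total` is the number of
#' cleavage observations the counts were collected from; each position's
#' counts sum to at most `total` (positions near substrate termini may
#' have fewer observations).
#'
#' @param protease_accession Protease accession the matrix belongs to.
#' @param counts Integer matrix, `k + m` rows by alphabet-size columns;
#'   column names are residue codes (default alphabet: the 20 standard
#'   residues).
#' @param nonprime Number of non-prime positions `k` (rows 1..k).
#' @param total Total number of cleavage observations `N`.
#' @return Object of class `specificity_matrix`.
#' @export
specificity_matrix <- function(protease_accession, counts, nonprime, total) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) colnames(counts) <- AA20[seq_len(ncol(counts))]
  k <- as.integer(nonprime)
  m <- nrow(counts) - k
  if (k < 0 || m < 0 || nrow(counts) < 1)
    abort("matrix for %s: nonprime=%d inconsistent with %d rows",
          protease_accession, k, nrow(counts))
  if (nrow(counts) > 8L)
    abort("matrix for %s: %d positions exceed the maximum window of 8",
          protease_accession, nrow(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    abort("matrix for %s: counts must be non-negative integers", protease_accession)
  if (!is_count(total) || total < 1)
    abort("matrix for %s: total observations must be a positive integer",
          protease_accession)
  if (any(rowSums(counts) > total))
    abort("matrix for %s: position counts exceed total observations (%d)",
          protease_accession, total)
  rownames(counts) <- position_labels(k, m)
  structure(list(protease_accession = protease_accession,
                 counts = counts, nonprime = k, prime = m,
                 total = as.integer(total)),
            class = "specificity_matrix")
}

position_labels <- function(k, m) {
  c(if (k > 0) paste0("P", k:1),
    if (m > 0) paste0("P", 1:m, "'"))
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat(sprintf("specificity_matrix for %s: P%d..P%d' (%d positions), N = %d\n",
              x$protease_accession, x$nonprime, x$prime,
              x$nonprime + x$prime, x$total))
  print(x$counts)
  invisible(x)
}

#' Is a specificity matrix usable for prediction?
#'
#' A matrix supports prediction when it rests on at least `min_cleavages`
#' observed cleavages, or when at least one position shows a residue
#' enriched at least `enrichment`-fold over the uniform expectation
#' (1/alphabet size) — i.e. the protease has a strong positional
#' preference even if observations are few.
#'
#' @param matrix A [specificity_matrix()].
#' @param min_cleavages Minimum observation count (default 40).
#' @param enrichment Minimum fold-enrichment over uniform (default 10).
#' @return `TRUE` or `FALSE`.
#' @export
matrix_usable <- function(matrix, min_cleavages = 40L, enrichment = 10) {
  stopifnot(inherits(matrix, "specificity_matrix"))
  if (matrix$total >= min_cleavages) return(TRUE)
  nres <- ncol(matrix$counts)
  freq <- matrix$counts / matrix$total
  any(freq >= enrichment / nres)
}

#' Normalize a specificity matrix into a probability matrix
#'
#' Divides each position's occurrence counts by the total number of
#' observations.  With `pseudocount = 0` this is the plain division
#' `count / N`; a positive pseudocount `c` (default 1, Laplace) yields
#' `(count + c) / (N + A c)` with `A` the alphabet size, guaranteeing
#' strictly positive probabilities and hence finite log-likelihood scores.
#'
#' @param matrix A [specificity_matrix()].
#' @param pseudocount Non-negative smoothing constant (default 1).
#' @param background Named numeric vector of background residue
#'   frequencies summing to 1; default uniform.
#' @return Object of class `probability_matrix`.
#' @export
to_probabilities <- function(matrix, pseudocount = 1, background = NULL) {
  stopifnot(inherits(matrix, "specificity_matrix"))
  if (matrix$total < 1) abort("matrix for %s has no observations",
                              matrix$protease_accession)
  if (pseudocount < 0) abort("pseudocount must be non-negative")
  A <- ncol(matrix$counts)
  probs <- (matrix$counts + pseudocount) / (matrix$total + A * pseudocount)
  if (is.null(background)) background <- setNames(rep(1 / A, A), colnames(matrix$counts))
  background <- background[colnames(matrix$counts)]
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1")
  probability_matrix(probs, matrix$nonprime,
                     protease_accession = matrix$protease_accession,
                     background = background, pseudocount = pseudocount)
}

#' Construct a probability matrix directly
#'
#' @param probs Numeric matrix of per-position residue probabilities (rows
#'   = positions `P<k>..P1, P1'..P<m>'`, columns named by residue); each
#'   row must sum to 1.
#' @param nonprime Number of non-prime positions.
#' @param protease_accession Optional owning protease accession.
#' @param background Named background frequencies (default uniform over
#'   the matrix's alphabet).
#' @param pseudocount Pseudocount used to produce `probs`, if any.
#' @return Object of class `probability_matrix`.
#' @export
probability_matrix <- function(probs, nonprime, protease_accession = NA_character_,
                               background = NULL, pseudocount = NA_real_) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) colnames(probs) <- AA20[seq_len(ncol(probs))]
  k <- as.integer(nonprime)
  m <- nrow(probs) - k
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    abort("each position's probabilities must sum to 1")
  if (is.null(background))
    background <- setNames(rep(1 / ncol(probs), ncol(probs)), colnames(probs))
  rownames(probs) <- position_labels(k, m)
  structure(list(protease_accession = protease_accession, probs = probs,
                 nonprime = k, prime = m, background = background,
                 pseudocount = pseudocount),
            class = "probability_matrix")
}

# Map a terminus window onto a probability matrix: the scissile bond is the
# anchor (window P1 aligns with matrix P1).  Returns a data.frame of
# (label, residue) for the positions covered by both the window and the
# matrix; truncated windows therefore contribute fewer positions.
align_window <- function(window, pmatrix) {
  np_w <- residues(window$nonprime)
  pr_w <- residues(window$prime)
  k <- min(length(np_w), pmatrix$nonprime)
  m <- min(length(pr_w), pmatrix$prime)
  labels <- character()
  res <- character()
  if (k > 0) {
    labels <- c(labels, paste0("P", k:1))
    res <- c(res, np_w[(length(np_w) - k + 1):length(np_w)])
  }
  if (m > 0) {
    labels <- c(labels, paste0("P", 1:m, "'"))
    res <- c(res, pr_w[1:m])
  }
  data.frame(label = labels, residue = res, stringsAsFactors = FALSE)
}

#' Log-likelihood score of a terminus window under a probability matrix
#'
#' The score is the natural-log likelihood ratio of the window's residues
#' under the matrix versus the background:
#' `sum over aligned positions of ln(p(residue, position) / background(residue))`.
#' The scissile bond anchors the alignment (window P1 against matrix P1);
#' truncated windows are scored over the available positions only.
#'
#' @param window A `terminus_window` (see [reconstruct_termini()]).
#' @param pmatrix A [probability_matrix()].
#' @return A single numeric score (natural log).
#' @export
loglik_score <- function(window, pmatrix) {
  al <- align_window(window, pmatrix)
  if (!nrow(al)) abort("window shares no positions with the matrix")
  unknown <- setdiff(al$residue, colnames(pmatrix$probs))
  if (length(unknown))
    abort("residue(s) outside the matrix alphabet: %s",
          paste(unknown, collapse = ", "))
  p <- pmatrix$probs[cbind(al$label, al$residue)]
  if (any(p <= 0))
    abort(paste("zero probability at an aligned position; rebuild the",
                "probability matrix with a positive pseudocount"))
  b <- pmatrix$background[al$residue]
  sum(log(p / b))
}

# Per-position log-likelihood values for a set of matrix row labels.
position_score_values <- function(pmatrix, labels) {
  lapply(labels, function(lb) {
    p <- pmatrix$probs[lb, ]
    if (any(p <= 0))
      abort(paste("zero probability in the matrix; rebuild with a positive",
                  "pseudocount before computing score distributions"))
    log(p / pmatrix$background[colnames(pmatrix$probs)])
  })
}

merge_support <- function(support, mass, tol) {
  o <- order(support)
  support <- support[o]
  mass <- mass[o]
  if (length(support) > 1L) {
    grp <- cumsum(c(TRUE, diff(support) > tol))
    ms <- rowsum(mass, grp, reorder = TRUE)[, 1]
    sv <- rowsum(support * mass, grp, reorder = TRUE)[, 1] / ms
    support <- unname(sv)
    mass <- unname(ms)
  }
  list(support = support, mass = mass)
}

#' Exact population distribution of log-likelihood scores
#'
#' Distribution of [loglik_score()] over all possible sequences at the
#' scored positions, each sequence weighted equally (`A^n` sequences for
#' alphabet size `A` and `n` positions).  Computed by iterated convolution
#' of the per-position score multisets, merging numerically identical
#' score values (tolerance `1e-12`).  When the exact support grows beyond
#' `max_support` points the merge tolerance is escalated tenfold until the
#' support fits, trading score resolution (well below any confidence-band
#' width) for bounded memory.
#'
#' @param pmatrix A [probability_matrix()].
#' @param labels Optional subset of position labels to marginalize to
#'   (used for truncated windows); default all positions.
#' @param max_support Support-size cap before coarsening (default 50000).
#' @return Object of class `score_distribution` with sorted `support` and
#'   matching `mass` (summing to 1).
#' @export
score_distribution <- function(pmatrix, labels = NULL, max_support = 50000L) {
  labels <- labels %||% rownames(pmatrix$probs)
  vals <- position_score_values(pmatrix, labels)
  A <- ncol(pmatrix$probs)
  support <- 0
  mass <- 1
  for (v in vals) {
    support <- as.vector(outer(support, v, `+`))
    mass <- as.vector(outer(mass, rep(1 / A, A), `*`))
    tol <- 1e-12
    merged <- merge_support(support, mass, tol)
    while (length(merged$support) > max_support) {
      tol <- tol * 10
      merged <- merge_support(merged$support, merged$mass, tol)
    }
    support <- merged$support
    mass <- merged$mass
  }
  structure(list(support = support, mass = mass / sum(mass)),
            class = "score_distribution")
}

#' Monte-Carlo estimate of the population score distribution
#'
#' Seeded sampling cross-check for [score_distribution()]: draws uniform
#' random sequences over the matrix alphabet and scores them.
#'
#' @inheritParams score_distribution
#' @param draws Number of sampled sequences (default 10000).
#' @param seed Integer seed.
#' @return Numeric vector of sampled scores.
#' @export
score_distribution_mc <- function(pmatrix, draws = 10000L, seed = 1L,
                                  labels = NULL) {
  labels <- labels %||% rownames(pmatrix$probs)
  vals <- position_score_values(pmatrix, labels)
  A <- ncol(pmatrix$probs)
  with_seed(seed, {
    draws_mat <- matrix(sample.int(A, draws * length(vals), replace = TRUE),
                        nrow = draws)
    rowSums(mapply(function(v, j) v[draws_mat[, j]], vals,
                   seq_along(vals)))
  })
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("score_distribution: %d support points in [%.4f, %.4f]\n",
              length(x$support), min(x$support), max(x$support)))
  invisible(x)
}

#' Percentile match threshold of a score distribution
#'
#' The threshold is the `percentile`-th percentile of the population score
#' distribution: the smallest support value whose cumulative mass reaches
#' `percentile / 100`.  A window is taken as statistically matched only
#' when its score lies strictly above this value — ties at the threshold
#' resolve toward non-match.
#'
#' @param dist A [score_distribution()].
#' @param percentile Percentile in (0, 100); default 99.
#' @return The threshold score.
#' @export
match_threshold <- function(dist, percentile = 99) {
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100)
    abort("percentile must lie strictly between 0 and 100")
  cdf <- cumsum(dist$mass)
  idx <- which(cdf >= percentile / 100 - 1e-12)[1]
  dist$support[idx]
}

# Strict match rule shared by prediction and threshold tests.
score_matches <- function(score, threshold) {
  isTRUE(score > threshold + 1e-9)
}

#' Percentile rank of a score in a distribution
#'
#' `100 * P(X <= score)`, ties included.
#'
#' @inheritParams match_threshold
#' @param score A score value.
#' @return Percentile rank in \[0, 100\].
#' @export
score_percentile <- function(score, dist) {
  100 * sum(dist$mass[dist$support <= score + 1e-9])
}

#' Default confidence-band boundaries
#'
#' Percentile-rank lower bounds of the low, medium and high confidence
#' bands.  These are declared configuration, not a claim about any
#' particular production tool's internals.
#'
#' @return Named numeric vector `c(low = 99, medium = 99.5, high = 99.9)`.
#' @export
confidence_bands <- function() c(low = 99, medium = 99.5, high = 99.9)

#' Assign a confidence level to a predicted score
#'
#' Bands the percentile rank of the score under the population score
#' distribution: `none` below the low band, then `low`, `medium`, `high`.
#'
#' @inheritParams score_percentile
#' @param bands Band boundaries as from [confidence_bands()].
#' @return One of `"none"`, `"low"`, `"medium"`, `"high"`.
#' @export
assign_confidence <- function(score, dist, bands = confidence_bands()) {
  r <- score_percentile(score, dist)
  if (r >= bands[["high"]]) "high"
  else if (r >= bands[["medium"]]) "medium"
  else if (r >= bands[["low"]]) "low"
  else "none"
}

# Cached per-(protease, position-subset) distribution lookup.
kb_score_distribution <- function(kb, acc, pmatrix, labels, params) {
  key <- paste(acc, paste(labels, collapse = ","), params$pseudocount, sep = "#")
  d <- kb$cache[[key]]
  if (is.null(d)) {
    d <- score_distribution(pmatrix, labels = labels,
                            max_support = params$max_support %||% 50000L)
    assign(key, d, envir = kb$cache)
  }
  d
}

kb_probability_matrix <- function(kb, acc, params) {
  key <- paste0("pm#", acc, "#", params$pseudocount)
  pm <- kb$cache[[key]]
  if (is.null(pm)) {
    pm <- to_probabilities(kb$matrices[[acc]], pseudocount = params$pseudocount)
    assign(key, pm, envir = kb$cache)
  }
  pm
}

#' Predict proteases for an unmatched terminus window
#'
#' For every usable specificity matrix in the knowledge base
#' ([matrix_usable()]), scores the window with [loglik_score()] and keeps
#' the proteases whose score exceeds their matrix's percentile match
#' threshold.  Truncated windows are scored over their available positions
#' with thresholds recomputed from the correspondingly marginalized score
#' distribution, keeping the percentile semantics coherent.
#'
#' @param window A `terminus_window` not at a protein terminus.
#' @param peptide The peptide input row the window belongs to.
#' @param kb A `cleavage_kb`.
#' @param percentile Match percentile (default 99).
#' @param pseudocount Pseudocount for probability matrices (default 1).
#' @param min_cleavages,enrichment Matrix usability rule parameters.
#' @param bands Confidence-band boundaries.
#' @param rescue Internal: marks emitted events as rescue events.
#' @return Event data.frame (possibly empty), sorted by descending
#'   percentile then protease accession.
#' @export
predict_cleavage <- function(window, peptide, kb, percentile = 99,
                             pseudocount = 1, min_cleavages = 40L,
                             enrichment = 10, bands = confidence_bands(),
                             rescue = FALSE) {
  stopifnot(inherits(kb, "cleavage_kb"))
  if (window$at_protein_terminus)
    abort("window at a protein terminus has no scissile bond to predict")
  params <- list(pseudocount = pseudocount)
  out <- empty_events()
  parent <- kb_protein(kb, peptide$parent_accession)
  for (acc in names(kb$matrices)) {
    if (!matrix_usable(kb$matrices[[acc]], min_cleavages, enrichment)) next
    pm <- kb_probability_matrix(kb, acc, params)
    al <- align_window(window, pm)
    if (!nrow(al)) next
    dist <- kb_score_distribution(kb, acc, pm, al$label, params)
    s <- loglik_score(window, pm)
    t <- match_threshold(dist, percentile)
    if (!score_matches(s, t)) next
    out <- rbind(out, event_row(
      peptide_id = peptide$peptide_id, terminus = window$terminus,
      protease_accession = acc, substrate_accession = parent$accession,
      p1_position = window$p1_position, knowledge_status = "predicted",
      confidence = assign_confidence(s, dist, bands), score = s,
      percentile = score_percentile(s, dist), rescue = rescue))
  }
  if (nrow(out)) {
    out <- out[order(-out$percentile, out$protease_accession), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Second-pass prediction assuming exopeptidase trimming
#'
#' When a terminus obtains no prediction (or only a low/medium-confidence
#' one), the free extremity may have been trimmed by an exopeptidase after
#' the initial endopeptidase cut.  For trims `t = 1..max_trim` the
#' hypothesized endopeptidase bond is shifted outward (N terminus:
#' `p1 - t`; C terminus: `p1 + t`), the window rebuilt at the shifted bond
#' and prediction re-run.  A rescue succeeds at the first `t` that yields
#' matrix matches, provided the exopeptidase catalog contains at least one
#' aminopeptidase (N terminus) or carboxypeptidase (C terminus).  The
#' endopeptidase events are emitted with `rescue = TRUE` and paired via
#' `partner_event_id` with one event per compatible catalog exopeptidase.
#'
#' @inheritParams predict_cleavage
#' @param max_trim Maximum residues assumed trimmed (default 2).
#' @param flank Window flank used to rebuild shifted windows.
#' @return Event data.frame (possibly empty).
#' @export
exopeptidase_rescue <- function(window, peptide, kb, max_trim = 2L,
                                flank = 4L, percentile = 99, pseudocount = 1,
                                min_cleavages = 40L, enrichment = 10,
                                bands = confidence_bands()) {
  stopifnot(inherits(kb, "cleavage_kb"))
  exo_type <- if (window$terminus == "N") "aminopeptidase" else "carboxypeptidase"
  exo_accs <- names(kb$exopeptidase_catalog)[kb$exopeptidase_catalog == exo_type]
  if (!length(exo_accs)) return(empty_events())
  exo_accs <- sort(exo_accs)
  parent <- kb_protein(kb, peptide$parent_accession)
  L <- nchar(parent$sequence)
  for (t in seq_len(max_trim)) {
    p1s <- if (window$terminus == "N") window$p1_position - t
           else window$p1_position + t
    if (p1s < 1L || p1s >= L) next
    w <- bond_window(parent, p1s, as.integer(flank), window$terminus)
    ev <- predict_cleavage(w, peptide, kb, percentile = percentile,
                           pseudocount = pseudocount,
                           min_cleavages = min_cleavages,
                           enrichment = enrichment, bands = bands,
                           rescue = TRUE)
    if (!nrow(ev)) next
    # pair the top-ranked endopeptidase event with each compatible exopeptidase
    exo <- do.call(rbind, lapply(exo_accs, function(acc)
      event_row(peptide_id = peptide$peptide_id, terminus = window$terminus,
                protease_accession = acc,
                substrate_accession = parent$accession,
                p1_position = window$p1_position,
                knowledge_status = "predicted",
                confidence = ev$confidence[1], rescue = TRUE,
                partner_event_id = ev$event_id[1])))
    ev$partner_event_id[1] <- paste(exo$event_id, collapse = ";")
    out <- rbind(ev, exo)
    rownames(out) <- NULL
    return(out)
  }
  empty_events()
}
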