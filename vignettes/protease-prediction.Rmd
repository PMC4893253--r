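---
title: "Predicting proteases from peptide termini: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting proteases from peptide termini: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Body fluids contain thousands of naturally occurring peptides produced by
proteolysis.  Knowing a peptide's boundaries on its parent protein, one can
ask which proteases plausibly generated it.  protcleave answers that
question in four stages, mirroring how peptide-centric protease-prediction
tools operate:

1. **Terminus reconstruction.**  A peptide reported as `(parent, start,
   end)` (1-based, inclusive) implies two candidate scissile bonds: one
   between residues `start - 1` and `start` (the N-terminal cleavage; the
   peptide's first residue is P1' of that site) and one between `end` and
   `end + 1` (the C-terminal cleavage; the last residue is P1).  Around
   each bond the cleavage-site window is rebuilt from the parent sequence:
   up to four non-prime residues (P4..P1, toward the substrate's
   N-terminus) and four prime residues (P1'..P4'), eight in total, or
   fewer when the bond lies near the beginning or end of the protein.  A
   peptide starting at residue 1 or ending at the last residue has no
   scissile bond at that terminus and generates no window there: a
   protein terminus is not proteolysis.
2. **Observed matching.**  Each window is compared against curated
   protease/cleavage-site associations.  A cleavage site is anchored to a
   substrate position, so the detailed match requires both substrate
   identity and P1-position identity; a fast prefilter on the residues
   flanking the bond (and sequence agreement over all shared positions)
   keeps this cheap.  Matches become *observed* proteolysis events.
3. **Matrix prediction.**  Windows that remain unmatched are scored
   against each protease's specificity matrix — per-position amino-acid
   occurrence counts over its known cleavages.  Counts are normalized to
   probabilities by dividing by the total number of observations `N`
   (optionally smoothed, see below), and the window score is the
   log-likelihood ratio

   $$ S(w) = \sum_{p \in \text{positions}} \ln \frac{\Pr(w_p \mid p)}{b(w_p)} $$

   with uniform background $b = 1/20$ by default.  A window is taken as
   statistically matched when its score lies strictly above the 99th
   percentile of the score population over *all possible sequences* at
   those positions, and a confidence level (low / medium / high) is
   banded from the score's percentile rank in that population.  A matrix
   is used only when it rests on at least 40 cleavages, or shows at least
   one position with a residue enriched ten-fold over the uniform
   expectation — weak matrices support no inference.
4. **Exopeptidase rescue and context validation.**  A terminus with no
   (or only a low/medium-confidence) prediction may have been trimmed by
   an exopeptidase after the initial endopeptidase cut.  The bond is
   therefore shifted outward by 1..`max_trim` residues, the window
   rebuilt and rescored; a successful shifted match is reported as a
   rescue pair — the endopeptidase event plus one event per catalogued
   aminopeptidase (N terminus) or carboxypeptidase (C terminus).
   Finally, every event is corroborated (or not) by two context checks:
   the protease and substrate share their taxon, and their GO
   cellular-component annotations intersect.  The verdict is reported
   alongside the event and never alters it — corroboration is reason to
   interpret a result with more confidence, not a filter.

The knowledge model behind these stages (proteins with GO annotation
facets, an `is_a` GO graph, taxa, cleavage-site records, matrices,
amino-acid properties, an exopeptidase catalog) is queryable through six
competency questions (`cq_*` functions): proteases and their sites, sites
explaining a peptide, a protein's function/taxon/location, a protease's
specificity, residue biochemistry and interchangeability, and a
protease's functions and processes.  A protein *is* a protease exactly
when one of its molecular-function annotations equals or descends from
peptidase activity (`GO:0008233`); endo-, exo-, amino- and
carboxypeptidase classes are anchored analogously in the
catalytic-activity hierarchy.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `flank` | 4 | residues per side of the bond (window of 8, matching P4..P4' matrices); 1..4 since motifs span two to eight residues |
| `percentile` | 99 | population percentile a score must strictly exceed to match |
| `bands` | 99 / 99.5 / 99.9 | percentile-rank lower bounds of the low / medium / high confidence bands |
| `pseudocount` | 1 | Laplace smoothing of the count/`N` division: `(count + c) / (N + 20c)`; 0 reproduces the plain division exactly |
| `min_cleavages` | 40 | observation floor of the matrix usability rule |
| `enrichment` | 10 | fold-enrichment alternative of the usability rule |
| `max_trim` | 2 | maximum residues assumed removed by an exopeptidase |
| `monte_carlo_draws` | 10000 | draws for the sampling cross-check of the score distribution |

The confidence-band boundaries and the OR reading of the "40 cleavages
and/or 10-fold enrichment" rule are declared configuration of this
package, not claims about any other tool's internals, which are not
published.

## Numerical choices

* **Log base.**  Natural log.  Scores are only ever compared within one
  matrix, so the base is inert; it is fixed for reproducibility.
* **Score population.**  "All possible sequences" is taken literally:
  each of the $20^n$ sequences at the scored positions weighs equally.
  The distribution is computed exactly by convolving the per-position
  score multisets, merging support values closer than $10^{-12}$.  When
  the support would exceed 50 000 points, the merge tolerance escalates
  tenfold until it fits; the induced threshold error is orders of
  magnitude below the confidence-band widths.  For small alphabets and
  few positions (≤ 4 × 4) no coarsening ever triggers and the result
  equals brute-force enumeration exactly, which the test suite verifies.
  A seeded Monte-Carlo mode (`score_distribution_mc()`) cross-checks the
  convolution.
* **Threshold and ties.**  The match threshold is the smallest support
  value whose cumulative mass reaches the percentile; a window matches
  only when its score is *strictly* above it, so ties resolve toward
  non-match and a degenerate (e.g. uniform-matrix) distribution can
  never match anything.
* **Truncated windows.**  Scored over their available positions only,
  against a threshold recomputed from the correspondingly marginalized
  distribution — percentile semantics stay coherent for short windows.
  Whether the original tools skip or rescale truncated windows is
  unknown; this behaviour is this package's own choice.
* **Degenerate inputs.**  Zero-probability cells are refused at scoring
  time with instructions to use a positive pseudocount; matrices whose
  position counts do not sum to `N` are rejected when normalized, since
  their "probabilities" would not form a distribution.
* **Determinism.**  The prediction pipeline draws no random numbers;
  knowledge bases are canonically ordered on load, so identical inputs
  give byte-identical result and axiom files.  All generator randomness
  flows from one explicit seed.

## The synthetic-data generator

`generate_kb()` emulates the statistical structure the method relies on:
uniform random substrate sequences; proteases annotated into the
peptidase hierarchy; specificity matrices drawn as multinomial counts
(`N = 60` observations by default, above the usability floor) from a
per-position preference distribution with strength in `[0, 1]` (0 =
uniform composition, 1 = single-residue positions — strength maps
monotonically to expected prediction power); observed cleavage-site
records planted at reserved substrate positions, whose stored sequences
are the substrate's own substrings; and *predictable* sites planted by
writing matrix-sampled residues into the sequence, which exercise the
prediction stage without entering the observed table.  A manifest of
every planted truth allows any prediction run to be scored without
reading generator internals.  `example_human_kb()` additionally ships a
four-protein human fixture (MMP-2 / serum albumin, neutrophil elastase /
ABCA6) whose annotation structure reproduces a known co-location
contrast: the first pair shares nucleus, extracellular region and
extracellular space; the second shares only its taxon.  Its sequences
are synthetic — only the annotation structure is meaningful.

What the generator does **not** emulate: real amino-acid composition
biases, MEROPS matrix marginals, UniProt annotation density, isoforms,
or signal-peptide coordinate shifts.  Passing tests therefore demonstrate
the correctness and calibration of the machinery (e.g. that random
windows match at about 1% of matrix tests at the 99th percentile, and
that matrix-sampled sites are re-attributed to their generating protease),
not recall on real peptidomics data, which depends entirely on the
curated knowledge supplied.

Test and benchmark problem sizes — a dozen 400-residue substrates, five
matrices, 100 observed-recovery cases, 200 power cases, 2 000 random
calibration peptides — were chosen as the smallest sizes at which the
binomial error bars are informative.

## Known limitations

* Cleavage-site knowledge is a hard limitation: a protease without a
  usable matrix can never be predicted, and absence of corroborating
  annotation is not evidence of absence.
* Classification ignores annotation evidence codes; all annotations
  weigh equally.
* Mapping cleavages to peptidase families (rather than single enzymes)
  is not supported.
* Co-location intersects leaf annotations by default; `propagate = TRUE`
  offers an `is_a`-closure mode, but part-of relations are not modelled.
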