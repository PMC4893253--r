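# protcleave

Protease prediction from peptide termini, for peptidomics.

Naturally occurring peptides in body fluids are cleavage fragments: each
terminus of a peptide marks a scissile bond that some protease hydrolyzed.
Given a peptide's coordinates on its parent protein, `protcleave`
reconstructs the cleavage-site windows around both bonds — up to four
non-prime (P4..P1) and four prime (P1'..P4') residues, written
(Pn..)P1–P1'(..Pn') with the bond between P1 and P1' — and traces each
window back to candidate proteases:

1. **Observed matching** against curated protease/cleavage-site
   associations anchored at substrate positions.
2. **Specificity-matrix prediction** for unmatched windows: each
   protease's per-position amino-acid counts are normalized to
   probabilities (count / *N* observations, optionally Laplace-smoothed)
   and the window scored by the log-likelihood ratio
   *S* = Σₚ ln( p(wₚ | p) / b(wₚ) ) against a uniform background.  A
   window matches when *S* lies strictly above the 99th percentile of the
   exact score distribution over all possible sequences (computed by
   convolution), and its percentile rank is banded into low / medium /
   high confidence.  Matrices backed by fewer than 40 cleavages and
   lacking a 10-fold-enriched position are excluded.
3. **Exopeptidase rescue** for termini that remain weakly explained,
   shifting the hypothesized endopeptidase bond outward by up to two
   residues and pairing any recovered match with catalogued amino-/
   carboxypeptidases.
4. **Context validation**: each event is corroborated (reported, never
   filtered) when protease and substrate share their taxon and at least
   one GO cellular-component annotation.

Behind the pipeline sits a compact knowledge model — proteins with GO
annotation facets, an `is_a` GO graph, taxa, cleavage sites, matrices,
amino-acid biochemistry, an exopeptidase catalog — exposed through six
competency queries (`cq_proteases_and_sites()`, `cq_sites_for_peptide()`,
`cq_context()`, `cq_specificity()`, `cq_aa_properties()` /
`interchangeable()`, `cq_functions_processes()`), plus an axiom-pattern
export rendering the knowledge base and event ledger in a Manchester-like
syntax.  A protein counts as a protease exactly when a molecular-function
annotation equals or descends from peptidase activity (`GO:0008233`).

## Worked example

Everything below is generated in code — a seeded synthetic knowledge base
with planted ground truth, and two peptides whose N-terminal windows were
sampled from known specificity matrices:

```r
library(protcleave)
gen <- generate_kb("readme_kb", seed = 42)
kb  <- build_kb(gen$bundle)
pep <- generate_peptides(kb, gen$manifest, "matrix-sampled", n = 2, seed = 42)
res <- predict_peptides(kb, pep$peptides)
res$events[, c("peptide_id","terminus","protease_accession","p1_position",
               "knowledge_status","confidence","score","percentile","verdict")]
```

```
[input] 2 peptides, 4 cleavage windows (0 protein termini skipped)
[observed] 0 observed matches
[predicted] 2 predictions, 2 rescue events
[validated] 3 of 4 events corroborated by taxon and co-location
  peptide_id terminus protease_accession p1_position knowledge_status
1   pepM0001        N           PR:PRX03         176        predicted
2   pepM0002        N           PR:PRX05          96        predicted
3   pepM0002        C           PR:PRX05         112        predicted
4   pepM0002        C          PR:EXOC01         111        predicted
  confidence     score percentile        verdict
1       high 15.102891  100.00000   corroborated
2       high 21.071847  100.00000   corroborated
3     medium  2.370718   99.83421   corroborated
4     medium        NA         NA uncorroborated
```

Both N termini are re-attributed to their true generating proteases
(`gen$manifest` records `PR:PRX03` at bond 176 and `PR:PRX05` at bond 96)
with high confidence: their scores sit at the top of the population
distribution.  The second peptide's C terminus gets a medium-confidence
prediction, so a rescue attempt also reports a paired carboxypeptidase
hypothesis (`PR:EXOC01`, no score of its own).  `write_events()` writes
the table, with validation columns, as TSV; `export_axioms()` renders the
run as axiom patterns.

A four-protein human fixture, `example_human_kb()`, reproduces a classic
co-location contrast: MMP-2 (`PR:P08253`) and serum albumin
(`PR:P02768`) share taxon `NCBI:9606` and three cellular components
(nucleus `GO:0005634`, extracellular region `GO:0005576`, extracellular
space `GO:0005615`), corroborating their observed cleavage, while
neutrophil elastase (`PR:P08246`) and ABCA6 (`PR:Q8N139`) share their
taxon but no location.

A command-line wrapper is installed at `inst/cli/protcleave`
(sub-commands `build-kb`, `predict`, `validate`, `query`,
`export-axioms`, `simulate`); `cleave_cli()` drives the same interface
in-process.

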