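test_that("protease recognition follows the peptidase-activity hierarchy", {
  go <- tiny_go()
  direct <- protein_record("PR:A", "ACDEF", functions = "GO:0008233")
  child <- protein_record("PR:B", "ACDEF", functions = "GO:0008238")
  none <- protein_record("PR:C", "ACDEF")
  expect_true(is_protease(direct, go))
  expect_true(is_protease(child, go))
  expect_false(is_protease(none, go))
  bad <- protein_record("PR:D", "ACDEF", functions = "GO:9999999")
  expect_error(is_protease(bad, go), "GO:9999999")
})

test_that("protease recognition is monotone under added descendant annotations", {
  go <- getFromNamespace("mini_go_graph", "protcleave")()
  descendants <- go_descendants(go, "GO:0008233")
  base_fns <- list(character(), "GO:0008233", "GO:0005215")
  for (fns in base_fns) {
    p0 <- protein_record("PR:M", "ACDEF", functions = fns)
    before <- is_protease(p0, go)
    for (d in descendants) {
      p1 <- protein_record("PR:M", "ACDEF", functions = c(fns, d))
      expect_true(is_protease(p1, go)) # adding a descendant never flips to FALSE
      if (before) expect_true(is_protease(p1, go))
    }
  }
})

test_that("protease classification exploits the catalytic-activity hierarchy", {
  go <- getFromNamespace("mini_go_graph", "protcleave")()
  exo <- protein_record("PR:A", "ACDEF", functions = "GO:0008238")
  expect_equal(classify_protease(exo, go), "exopeptidase")
  amino <- protein_record("PR:B", "ACDEF", functions = "GO:0004177")
  expect_equal(classify_protease(amino, go),
               c("aminopeptidase", "exopeptidase"))
  plain <- protein_record("PR:C", "ACDEF", functions = "GO:0008233")
  expect_equal(classify_protease(plain, go), character())
  not <- protein_record("PR:D", "ACDEF")
  expect_error(classify_protease(not, go), "not a protease")
})

test_that("proteases-and-sites query conserves stored records plus predictions", {
  gen <- default_gen()
  kb <- gen$kb
  tab <- cq_proteases_and_sites(kb)
  expect_equal(nrow(tab), nrow(kb$cleavage_sites))
  expect_true(all(tab$status == "observed"))

  pep <- generate_peptides(kb, gen$gen$manifest, "matrix-sampled", n = 2, seed = 9)
  res <- predict_peptides(kb, pep$peptides, quiet = TRUE)
  kb2 <- res$kb
  tab2 <- cq_proteases_and_sites(kb2)
  n_pred <- sum(kb2$events$knowledge_status == "predicted")
  expect_equal(nrow(tab2), nrow(kb2$cleavage_sites) + n_pred)
  expect_equal(nrow(cq_proteases_and_sites(kb2, "predicted")), n_pred)

  empty_kb <- knowledge_base(list(), tiny_go())
  expect_equal(nrow(cq_proteases_and_sites(empty_kb)), 0L)
})

test_that("peptide-site query flags protein termini and recovers planted sites", {
  gen <- default_gen()
  kb <- gen$kb
  acc <- names(kb$proteins)[1]
  L <- nchar(kb$proteins[[acc]]$sequence)
  whole <- list(peptide_id = "whole", parent_accession = acc, start = 1L, end = L)
  tab <- cq_sites_for_peptide(kb, whole)
  expect_equal(tab$status, c("protein-terminus", "protein-terminus"))

  site <- kb$cleavage_sites[1, ]
  pep <- list(peptide_id = "cut", parent_accession = site$substrate_accession,
              start = site$p1_position + 1L, end = site$p1_position + 10L)
  tab2 <- cq_sites_for_peptide(kb, pep)
  nrow_obs <- tab2[tab2$terminus == "N", ]
  expect_equal(nrow_obs$status, "observed")
  expect_equal(nrow_obs$protease, site$protease_accession)
  expect_equal(nrow_obs$site_sequence, site$site_sequence)

  expect_error(cq_sites_for_peptide(kb, list(peptide_id = "x",
                                             parent_accession = "PR:NOPE",
                                             start = 2L, end = 5L)),
               "unknown protein")
})

test_that("context and function/process queries return annotation facets verbatim", {
  ex <- example_kb()
  ctx <- cq_context(ex$kb, "PR:P02768")
  expect_true("GO:0005576" %in% ctx$locations)
  expect_equal(cq_context(ex$kb, "PR:P08253")$taxon, "NCBI:9606")

  fp <- cq_functions_processes(ex$kb, "PR:P08253")
  expect_true("GO:0006508" %in% fp$processes)
  expect_true("GO:0004222" %in% fp$functions)

  bare <- knowledge_base(list(protein_record("PR:B", "ACDEF")), tiny_go())
  expect_equal(cq_context(bare, "PR:B")$locations, character())
  expect_equal(cq_functions_processes(bare, "PR:B")$functions, character())
})

test_that("specificity query returns the stored matrix or nothing", {
  gen <- default_gen()
  m <- cq_specificity(gen$kb, "PR:PRX01")
  expect_s3_class(m, "specificity_matrix")
  expect_equal(nrow(m$counts), 8L)
  expect_null(cq_specificity(gen$kb, "PR:PRX_ABSENT"))
  expect_warning(out <- cq_specificity(gen$kb, "PR:SUB001"), "not a protease")
  expect_null(out)
})

test_that("amino-acid property queries answer charge and interchangeability", {
  gen <- default_gen()
  kb <- gen$kb
  expect_equal(cq_aa_properties(kb, "D")$charge, "negative")
  expect_equal(interchangeable(kb, "D", "charge"), c("D", "E"))
  expect_error(cq_aa_properties(kb, "X"), "unknown residue")
  # reflexivity across all residues and facets
  for (facet in c("charge", "polarity", "side_chain_class"))
    for (r in kb$aa_properties$residue)
      expect_true(r %in% interchangeable(kb, r, facet))
})

test_that("recording events is idempotent per (peptide, terminus, protease)", {
  gen <- default_gen()
  kb <- gen$kb
  site <- kb$cleavage_sites[1, ]
  ev <- getFromNamespace("event_row", "protcleave")(
    "pep1", "N", site$protease_accession, site$substrate_accession,
    site$p1_position, "observed")
  kb <- record_observed_event(kb, ev)
  expect_equal(nrow(kb$events), 1L)
  expect_warning(kb <- record_observed_event(kb, ev), "duplicate")
  expect_equal(nrow(kb$events), 1L)
  expect_error(record_observed_event(kb, transform(ev, knowledge_status = "predicted")))
})

test_that("stored site sequences must match the substrate substring on load", {
  go <- tiny_go()
  prot <- protein_record("PR:S", TOY_SEQ, functions = "GO:0008233")
  cs <- data.frame(substrate_accession = "PR:S", p1_position = 9L,
                   nonprime_length = 4L, site_sequence = "GHIKLMNP",
                   protease_accession = "PR:S", source = "curated-db",
                   stringsAsFactors = FALSE)
  expect_s3_class(knowledge_base(list(prot), go, cleavage_sites = cs),
                  "cleavage_kb")
  cs$site_sequence <- "AAAAAAAA"
  expect_error(knowledge_base(list(prot), go, cleavage_sites = cs),
               "stored sequence")
})
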