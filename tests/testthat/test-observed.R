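test_that("peptides cut at stored sites recover the stored protease", {
  gen <- default_gen()
  kb <- gen$kb
  site <- kb$cleavage_sites[3, ]
  pep <- list(peptide_id = "cut", parent_accession = site$substrate_accession,
              start = site$p1_position + 1L, end = site$p1_position + 12L)
  w <- reconstruct_termini(kb$proteins[[site$substrate_accession]], pep)$N
  ev <- match_observed(w, pep, kb)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$protease_accession, site$protease_accession)
  expect_equal(ev$knowledge_status, "observed")
  expect_equal(ev$p1_position, site$p1_position)
  expect_true(is.na(ev$score) && is.na(ev$percentile))
  expect_equal(ev$confidence, "not-applicable")
})

test_that("sequence identity on another protein passes the prefilter but not the detailed match", {
  go <- tiny_go()
  # identical motif at position 9 on both proteins; site stored only for PR:S1
  seq1 <- TOY_SEQ
  prot1 <- protein_record("PR:S1", seq1, functions = "GO:0008233")
  prot2 <- protein_record("PR:S2", seq1) # same sequence, different accession
  cs <- data.frame(substrate_accession = "PR:S1", p1_position = 9L,
                   nonprime_length = 4L, site_sequence = "GHIKLMNP",
                   protease_accession = "PR:S1", source = "literature",
                   stringsAsFactors = FALSE)
  kb <- knowledge_base(list(prot1, prot2), go, cleavage_sites = cs)
  pep2 <- list(peptide_id = "p", parent_accession = "PR:S2", start = 10L, end = 20L)
  w2 <- reconstruct_termini(prot2, pep2)$N
  expect_equal(nrow(match_observed(w2, pep2, kb)), 0L)
  # position mismatch on the right protein also rejects
  pep3 <- list(peptide_id = "q", parent_accession = "PR:S1", start = 11L, end = 20L)
  w3 <- reconstruct_termini(prot1, pep3)$N
  expect_equal(nrow(match_observed(w3, pep3, kb)), 0L)
})

test_that("matching against an empty cleavage-site table yields no events", {
  go <- tiny_go()
  prot <- protein_record("PR:S", TOY_SEQ)
  kb <- knowledge_base(list(prot), go)
  pep <- list(peptide_id = "p", parent_accession = "PR:S", start = 10L, end = 18L)
  w <- reconstruct_termini(prot, pep)$N
  expect_equal(nrow(match_observed(w, pep, kb)), 0L)
  expect_error(match_observed(reconstruct_termini(prot, list(peptide_id = "p",
                                                             start = 1L,
                                                             end = 18L))$N,
                              pep, kb), "protein terminus")
})

test_that("the prefilter is complete relative to a brute-force detailed matcher", {
  gen <- default_gen()
  kb <- gen$kb
  pepset <- generate_peptides(kb, gen$gen$manifest, "observed-cut",
                              n = 20, seed = 17)
  for (i in seq_len(nrow(pepset$peptides))) {
    pep <- pepset$peptides[i, ]
    parent <- kb$proteins[[pep$parent_accession]]
    for (term in c("N", "C")) {
      w <- reconstruct_termini(parent, pep)[[term]]
      if (w$at_protein_terminus) next
      got <- match_observed(w, pep, kb)
      want <- brute_force_observed(w, pep, kb)
      expect_setequal(got$protease_accession,
                      kb$cleavage_sites$protease_accession[want])
    }
  }
})

test_that("truncated windows match records truncated at the same boundary", {
  go <- tiny_go()
  prot <- protein_record("PR:S", TOY_SEQ, functions = "GO:0008233")
  # site at p1 = 2: only two non-prime residues exist
  cs <- data.frame(substrate_accession = "PR:S", p1_position = 2L,
                   nonprime_length = 2L, site_sequence = "ACDEFG",
                   protease_accession = "PR:S", source = "curated-db",
                   stringsAsFactors = FALSE)
  kb <- knowledge_base(list(prot), go, cleavage_sites = cs)
  pep <- list(peptide_id = "p", parent_accession = "PR:S", start = 3L, end = 20L)
  w <- reconstruct_termini(prot, pep)$N
  expect_true(w$truncated_nonprime)
  ev <- match_observed(w, pep, kb)
  expect_equal(nrow(ev), 1L)
})

test_that("multiple proteases observed at one site are all reported", {
  go <- tiny_go()
  prot <- protein_record("PR:S", TOY_SEQ, functions = "GO:0008233")
  cs <- rbind(
    data.frame(substrate_accession = "PR:S", p1_position = 9L,
               nonprime_length = 4L, site_sequence = "GHIKLMNP",
               protease_accession = "PR:S", source = "curated-db",
               stringsAsFactors = FALSE),
    data.frame(substrate_accession = "PR:S", p1_position = 9L,
               nonprime_length = 4L, site_sequence = "GHIKLMNP",
               protease_accession = "PR:S2", source = "literature",
               stringsAsFactors = FALSE))
  prot2 <- protein_record("PR:S2", "ACDEFK", functions = "GO:0008238")
  kb <- knowledge_base(list(prot, prot2), go, cleavage_sites = cs)
  pep <- list(peptide_id = "p", parent_accession = "PR:S", start = 10L, end = 20L)
  w <- reconstruct_termini(prot, pep)$N
  ev <- match_observed(w, pep, kb)
  expect_equal(ev$protease_accession, c("PR:S", "PR:S2")) # sorted
})
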