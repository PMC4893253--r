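test_that("FASTA parsing handles the UniProt header convention and validates residues", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P02768|ALBU_HUMAN Serum albumin", "ACDEFGHIKL"), path)
  fa <- read_fasta(path)
  expect_equal(fa$accession, "P02768")
  expect_equal(fa$alt_id, "ALBU_HUMAN")
  expect_equal(nchar(fa$sequence), 10L)

  writeLines(c(">P1 test", "ACDXFG"), path)
  expect_error(read_fasta(path), "position 4")

  writeLines(character(), path)
  expect_warning(fa0 <- read_fasta(path), "empty")
  expect_equal(nrow(fa0), 0L)

  writeLines(c(">A", "ACDE", ">A", "ACDE"), path)
  expect_error(read_fasta(path), "duplicate")
})

test_that("annotation reader validates facets and GO namespaces", {
  go <- tiny_go()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("! comment", "accession\tterm\tfacet",
               "P02768\tGO:0005634\tcellular_component"), path)
  ann <- read_annotations(path, go = go)
  expect_equal(ann$term, "GO:0005634")

  writeLines(c("! only comments here"), path)
  expect_equal(nrow(read_annotations(path)), 0L)

  writeLines(c("accession\tterm\tfacet",
               "P02768\tGO:0005634\tmolecular_function"), path)
  expect_error(read_annotations(path, go = go), "namespace")

  writeLines(c("accession\tterm\tfacet",
               "P02768\tGO:9999999\tcellular_component"), path)
  expect_error(read_annotations(path, go = go), "unknown GO term")
})

test_that("matrix files roundtrip and malformed blocks are rejected", {
  gen <- default_gen()
  ms <- gen$kb$matrices
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrices <- getFromNamespace("write_matrices", "protcleave")
  write_matrices(ms, path)
  ms2 <- read_matrices(path)
  expect_equal(names(ms2), names(ms))
  expect_equal(ms2[[1]]$counts, ms[[1]]$counts)
  expect_equal(ms2[[1]]$total, ms[[1]]$total)
  expect_equal(nrow(ms2[[1]]$counts), 8L)

  expect_error(read_matrix(path), "exactly one")

  # declared nonprime inconsistent with row labels
  lines <- readLines(path)
  first_block_end <- grep("^#protease=", lines)[2] - 1L
  block <- lines[1:first_block_end]
  block[1] <- sub("nonprime=4", "nonprime=3", block[1])
  writeLines(block, path)
  expect_error(read_matrices(path), "row labels")

  # negative count
  block[1] <- sub("nonprime=3", "nonprime=4", block[1])
  block[3] <- sub("^(P4\t)\\d+", "\\1-1", block[3])
  writeLines(block, path)
  expect_error(read_matrices(path), "non-negative")
})

test_that("taxon reader derives lineages and rejects broken parent links", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tname\tparent_id",
               "NCBI:2759\tEukaryota\t",
               "NCBI:33208\tMetazoa\tNCBI:2759",
               "NCBI:9606\tHomo sapiens\tNCBI:33208"), path)
  taxa <- read_taxa(path)
  expect_equal(taxa[["NCBI:9606"]]$lineage, c("NCBI:33208", "NCBI:2759"))

  writeLines(c("taxon_id\tname\tparent_id",
               "NCBI:9606\tHomo sapiens\tNCBI:40674"), path)
  expect_error(read_taxa(path), "not defined")
})

test_that("build_kb aggregates every validation failure into one report", {
  gen <- default_gen()
  dir <- withr::local_tempdir()
  file.copy(list.files(gen$gen$dir, full.names = TRUE), dir)
  # corrupt one stored site sequence and attach a matrix to a non-protease
  cs_path <- file.path(dir, "cleavage_sites.tsv")
  cs <- readLines(cs_path)
  cs[2] <- sub("\t([A-Z]{8})\t", "\tAAAAAAAA\t", cs[2])
  writeLines(cs, cs_path)
  m_path <- file.path(dir, "matrices.tsv")
  m <- readLines(m_path)
  m[1] <- sub("protease=PR:PRX01", "protease=PR:SUB001", m[1])
  writeLines(m, m_path)
  err <- tryCatch(build_kb(dir), error = conditionMessage)
  expect_match(err, "stored sequence")
  expect_match(err, "protease definition")
})

test_that("build_kb is deterministic under file row reordering", {
  gen <- default_gen()
  dir <- withr::local_tempdir()
  file.copy(list.files(gen$gen$dir, full.names = TRUE), dir)
  ann_path <- file.path(dir, "annotations.tsv")
  ann <- readLines(ann_path)
  writeLines(c(ann[1], rev(ann[-1])), ann_path)
  cs_path <- file.path(dir, "cleavage_sites.tsv")
  cs <- readLines(cs_path)
  writeLines(c(cs[1], rev(cs[-1])), cs_path)
  kb2 <- build_kb(dir)
  kb1 <- gen$kb
  expect_equal(kb2$cleavage_sites, kb1$cleavage_sites)
  expect_equal(lapply(kb2$proteins, `[[`, "locations"),
               lapply(kb1$proteins, `[[`, "locations"))
})

test_that("event tables roundtrip through the results TSV", {
  gen <- default_gen()
  pep <- generate_peptides(gen$kb, gen$gen$manifest, "observed-cut",
                           n = 3, seed = 5)
  res <- predict_peptides(gen$kb, pep$peptides, quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(res$events, path)
  back <- read_events(path)
  expect_equal(back$event_id, res$events$event_id)
  expect_equal(back$p1_position, res$events$p1_position)
  expect_equal(back$score, res$events$score)
  expect_equal(back$verdict, res$events$verdict)

  write_events(empty_events(), path)
  expect_equal(nrow(read_events(path)), 0L)
  expect_equal(length(readLines(path)), 1L) # header only
})

test_that("peptide input coordinates are validated on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide_id\taccession\tstart\tend",
               "p1\tPR:X\t10\t18"), path)
  pep <- read_peptides(path)
  expect_equal(pep$start, 10L)
  writeLines(c("peptide_id\taccession\tstart\tend",
               "p1\tPR:X\t18\t10"), path)
  expect_error(read_peptides(path), "invalid coordinates")
})
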