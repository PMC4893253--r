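# Seeded generators of complete knowledge-base bundles with a manifest of
# planted ground truth.  All randomness flows from the single explicit
# seed argument; re-running with the same seed writes byte-identical
# bundles.

# The packaged mini GO graph: the molecular-function peptidase hierarchy
# needed for protease classification, the proteolysis branch of
# biological_process and a set of cellular components for co-location.
mini_go_graph <- function() {
  t <- list(
    list("GO:0003674", "molecular_function", "molecular_function", character()),
    list("GO:0003824", "catalytic activity", "molecular_function", "GO:0003674"),
    list("GO:0016787", "hydrolase activity", "molecular_function", "GO:0003824"),
    list("GO:0008233", "peptidase activity", "molecular_function", "GO:0016787"),
    list("GO:0004175", "endopeptidase activity", "molecular_function", "GO:0008233"),
    list("GO:0008238", "exopeptidase activity", "molecular_function", "GO:0008233"),
    list("GO:0004177", "aminopeptidase activity", "molecular_function", "GO:0008238"),
    list("GO:0004180", "carboxypeptidase activity", "molecular_function", "GO:0008238"),
    list("GO:0004222", "metalloendopeptidase activity", "molecular_function", "GO:0004175"),
    list("GO:0004252", "serine-type endopeptidase activity", "molecular_function", "GO:0004175"),
    list("GO:0005215", "transporter activity", "molecular_function", "GO:0003674"),
    list("GO:0008150", "biological_process", "biological_process", character()),
    list("GO:0008152", "metabolic process", "biological_process", "GO:0008150"),
    list("GO:0019538", "protein metabolic process", "biological_process", "GO:0008152"),
    list("GO:0006508", "proteolysis", "biological_process", "GO:0019538"),
    list("GO:0055085", "transmembrane transport", "biological_process", "GO:0008150"),
    list("GO:0005575", "cellular_component", "cellular_component", character()),
    list("GO:0005634", "nucleus", "cellular_component", "GO:0005575"),
    list("GO:0005576", "extracellular region", "cellular_component", "GO:0005575"),
    list("GO:0005615", "extracellular space", "cellular_component", "GO:0005576"),
    list("GO:0005737", "cytoplasm", "cellular_component", "GO:0005575"),
    list("GO:0005739", "mitochondrion", "cellular_component", "GO:0005737"),
    list("GO:0005764", "lysosome", "cellular_component", "GO:0005737"),
    list("GO:0005886", "plasma membrane", "cellular_component", "GO:0016020"),
    list("GO:0016020", "membrane", "cellular_component", "GO:0005575"))
  go_graph(id = vapply(t, `[[`, "", 1L), name = vapply(t, `[[`, "", 2L),
           namespace = vapply(t, `[[`, "", 3L),
           parents = lapply(t, `[[`, 4L))
}

default_taxa <- function() {
  list("NCBI:2759" = taxon_node("NCBI:2759", "Eukaryota"),
       "NCBI:33208" = taxon_node("NCBI:33208", "Metazoa", "NCBI:2759"),
       "NCBI:40674" = taxon_node("NCBI:40674", "Mammalia",
                                 c("NCBI:33208", "NCBI:2759")),
       "NCBI:9606" = taxon_node("NCBI:9606", "Homo sapiens",
                                c("NCBI:40674", "NCBI:33208", "NCBI:2759")),
       "NCBI:10090" = taxon_node("NCBI:10090", "Mus musculus",
                                 c("NCBI:40674", "NCBI:33208", "NCBI:2759")))
}

random_sequence <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

# Concentrated per-position preference: strength 0 is the uniform
# composition, strength 1 concentrates all probability on one preferred
# residue per position.
strength_probs <- function(strength, preferred) {
  p <- rep((1 - strength) / 20, 20)
  names(p) <- AA20
  p[preferred] <- p[preferred] + strength
  p
}

#' Generate a complete synthetic knowledge-base bundle
#'
#' Writes a seeded, fully self-consistent bundle to `dir` (the standard
#' file names of [kb_bundle_from_dir()]) together with a manifest of
#' every planted truth.  Substrate sequences are uniform random over the
#' 20-letter alphabet.  Each protease gets a specificity matrix whose
#' per-position counts are multinomial draws from a preference
#' distribution of the given strength (0 = uniform composition, 1 =
#' single-residue positions).  Observed cleavage sites are planted at
#' random substrate positions (the site sequence is the substrate's own
#' substring, so every record verifies); predictable sites are planted by
#' overwriting the substrate window with residues sampled from the
#' owning matrix's probability matrix, giving ground truth for
#' prediction-power checks without entering the observed table.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all randomness.
#' @param n_substrates Number of substrate proteins (default 12).
#' @param n_proteases Number of matrix-bearing endopeptidases (default 5).
#' @param n_sites Number of planted observed cleavage-site records
#'   (default 30).
#' @param matrix_strengths Preference strength per protease in `[0, 1]`,
#'   recycled to `n_proteases` (default 0.9).
#' @param matrix_total Observation count `N` behind each matrix (default
#'   60, comfortably above the 40-cleavage usability rule).
#' @param n_predictable Planted matrix-sampled sites per protease
#'   (default 3).
#' @param protein_length Substrate length in residues (default 400).
#' @param mouse_every Every `mouse_every`-th substrate is assigned the
#'   mouse taxon instead of human (default 5; 0 disables).
#' @return List with `dir`, the [kb_bundle()], and `manifest` (data
#'   frames `proteins`, `sites`, `predictable`, `matrices`).
#' @export
generate_kb <- function(dir, seed = 1L, n_substrates = 12L, n_proteases = 5L,
                        n_sites = 30L, matrix_strengths = 0.9,
                        matrix_total = 60L, n_predictable = 3L,
                        protein_length = 400L, mouse_every = 5L) {
  stopifnot(n_substrates >= 1, n_proteases >= 1, n_sites >= 0,
            protein_length >= 40)
  matrix_strengths <- rep_len(matrix_strengths, n_proteases)
  if (any(matrix_strengths < 0 | matrix_strengths > 1))
    abort("matrix_strengths must lie in [0, 1]")
  flank <- 4L
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(derive_seed(seed, 101L), {
    sub_acc <- sprintf("PR:SUB%03d", seq_len(n_substrates))
    prx_acc <- sprintf("PR:PRX%02d", seq_len(n_proteases))
    exo_acc <- c("PR:EXOA01", "PR:EXOC01")
    cc_pool <- c("GO:0005576", "GO:0005615", "GO:0005634", "GO:0005737",
                 "GO:0005739", "GO:0005764", "GO:0005886", "GO:0016020")
    seqs <- setNames(vapply(sub_acc, function(a) random_sequence(protein_length),
                            ""), sub_acc)
    taxon_of <- setNames(rep("NCBI:9606", n_substrates), sub_acc)
    if (mouse_every > 0) {
      mouse <- seq_len(n_substrates) %% mouse_every == 0
      taxon_of[mouse] <- "NCBI:10090"
    }

    # specificity matrices
    matrices <- list()
    preferred <- list()
    for (j in seq_len(n_proteases)) {
      pref <- sample(AA20, 8L, replace = TRUE)
      preferred[[prx_acc[j]]] <- pref
      counts <- t(vapply(seq_len(8L), function(pos)
        as.vector(stats::rmultinom(1, matrix_total,
                                   strength_probs(matrix_strengths[j], pref[pos]))),
        numeric(20)))
      colnames(counts) <- AA20
      matrices[[prx_acc[j]]] <- specificity_matrix(prx_acc[j], counts, 4L,
                                                   matrix_total)
    }

    # reserve non-overlapping bond positions per substrate
    occupied <- setNames(vector("list", n_substrates), sub_acc)
    reserve <- function(acc) {
      L <- nchar(seqs[[acc]])
      for (try in 1:200) {
        p1 <- sample(seq(flank + 3L, L - flank - 3L), 1L)
        if (!any(abs(unlist(occupied[[acc]]) - p1) < 12L) ||
            is.null(occupied[[acc]])) {
          if (is.null(occupied[[acc]]) ||
              !any(abs(unlist(occupied[[acc]]) - p1) < 12L)) {
            occupied[[acc]] <<- c(occupied[[acc]], p1)
            return(p1)
          }
        }
      }
      abort("could not place a site on %s: parameters infeasible (too dense)", acc)
    }

    # predictable (matrix-sampled) sites: overwrite the window residues
    predictable <- NULL
    for (j in seq_len(n_proteases)) {
      pm <- to_probabilities(matrices[[prx_acc[j]]], pseudocount = 0)
      for (r in seq_len(n_predictable)) {
        acc <- sample(sub_acc, 1L)
        p1 <- reserve(acc)
        window <- vapply(seq_len(8L), function(pos)
          sample(AA20, 1L, prob = pm$probs[pos, ]), "")
        s <- seqs[[acc]]
        substr(s, p1 - 3L, p1 + 4L) <- paste(window, collapse = "")
        seqs[[acc]] <- s
        predictable <- rbind(predictable, data.frame(
          protease = prx_acc[j], substrate = acc, p1_position = p1,
          stringsAsFactors = FALSE))
      }
    }

    # observed sites: the substrate's own substring around a reserved bond
    sites <- empty_cleavage_sites()
    if (n_sites > 0) {
      for (i in seq_len(n_sites)) {
        acc <- sample(sub_acc, 1L)
        p1 <- reserve(acc)
        prx <- sample(prx_acc, 1L)
        sites <- rbind(sites, data.frame(
          substrate_accession = acc, p1_position = p1, nonprime_length = 4L,
          site_sequence = substr1(seqs[[acc]], p1 - 3L, p1 + 4L),
          protease_accession = prx,
          source = sample(c("curated-db", "sequence-db", "literature"), 1L),
          stringsAsFactors = FALSE))
      }
    }

    # annotation table
    ann <- NULL
    add_ann <- function(acc, term, facet)
      ann <<- rbind(ann, data.frame(accession = acc, term = term,
                                    facet = facet, stringsAsFactors = FALSE))
    for (a in sub_acc) {
      add_ann(a, taxon_of[[a]], "taxon")
      for (cc in sample(cc_pool, 3L)) add_ann(a, cc, "cellular_component")
    }
    for (j in seq_len(n_proteases)) {
      a <- prx_acc[j]
      add_ann(a, "NCBI:9606", "taxon")
      add_ann(a, sample(c("GO:0004222", "GO:0004252"), 1L), "molecular_function")
      add_ann(a, "GO:0006508", "biological_process")
      for (cc in sample(cc_pool, 3L)) add_ann(a, cc, "cellular_component")
    }
    add_ann(exo_acc[1], "NCBI:9606", "taxon")
    add_ann(exo_acc[1], "GO:0004177", "molecular_function")
    add_ann(exo_acc[1], "GO:0006508", "biological_process")
    add_ann(exo_acc[1], "GO:0005576", "cellular_component")
    add_ann(exo_acc[2], "NCBI:9606", "taxon")
    add_ann(exo_acc[2], "GO:0004180", "molecular_function")
    add_ann(exo_acc[2], "GO:0006508", "biological_process")
    add_ann(exo_acc[2], "GO:0005576", "cellular_component")

    enzyme_len <- 120L
    fa <- data.frame(
      accession = c(sub_acc, prx_acc, exo_acc),
      alt_id = NA_character_,
      description = c(sub_acc, prx_acc, exo_acc),
      sequence = c(unname(seqs),
                   vapply(c(prx_acc, exo_acc),
                          function(a) random_sequence(enzyme_len), "")),
      stringsAsFactors = FALSE)

    write_fasta(fa, file.path(dir, "proteins.fasta"))
    write_obo(mini_go_graph(), file.path(dir, "go.obo"))
    write_annotations(ann, file.path(dir, "annotations.tsv"))
    write_taxa(default_taxa(), file.path(dir, "taxa.tsv"))
    write_cleavage_sites(sites, file.path(dir, "cleavage_sites.tsv"))
    write_matrices(matrices, file.path(dir, "matrices.tsv"))
    write_exopeptidase_catalog(
      setNames(c("aminopeptidase", "carboxypeptidase"), exo_acc),
      file.path(dir, "exopeptidase_catalog.tsv"))

    manifest <- list(
      proteins = data.frame(accession = fa$accession,
                            role = c(rep("substrate", n_substrates),
                                     rep("protease", n_proteases),
                                     "aminopeptidase", "carboxypeptidase"),
                            taxon = c(unname(taxon_of),
                                      rep("NCBI:9606", n_proteases + 2L)),
                            stringsAsFactors = FALSE),
      sites = sites,
      predictable = predictable %||%
        data.frame(protease = character(), substrate = character(),
                   p1_position = integer(), stringsAsFactors = FALSE),
      matrices = data.frame(protease = prx_acc, strength = matrix_strengths,
                            total = matrix_total, stringsAsFactors = FALSE))
    write_plain_tsv(manifest$sites, file.path(dir, "manifest_sites.tsv"))
    write_plain_tsv(manifest$predictable, file.path(dir, "manifest_predictable.tsv"))
    write_plain_tsv(manifest$proteins, file.path(dir, "manifest_proteins.tsv"))
    write_plain_tsv(manifest$matrices, file.path(dir, "manifest_matrices.tsv"))
    list(dir = dir, bundle = kb_bundle_from_dir(dir), manifest = manifest)
  })
}

#' Generate peptide inputs with ground truth
#'
#' Three modes: `observed-cut` peptides begin immediately after a planted
#' observed cleavage site (start = planted P1 + 1); `matrix-sampled`
#' peptides begin after a planted predictable site of a (optionally
#' named) protease; `random` peptides are uniform interior spans.  The
#' truth table records the generating protease, or none.
#'
#' @param kb A `cleavage_kb` built from a generated bundle.
#' @param manifest The manifest returned by [generate_kb()].
#' @param mode `"observed-cut"`, `"matrix-sampled"` or `"random"`.
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @param protease Optional protease filter for `matrix-sampled`.
#' @param peptide_length Peptide length in residues (default 15).
#' @return List with `peptides` (input table) and `truth`
#'   (`peptide_id`, `generating_protease`, `p1_position`).
#' @export
generate_peptides <- function(kb, manifest, mode = c("observed-cut",
                                                     "matrix-sampled",
                                                     "random"),
                              n, seed = 1L, protease = NULL,
                              peptide_length = 15L) {
  mode <- match.arg(mode)
  empty <- list(
    peptides = data.frame(peptide_id = character(),
                          parent_accession = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE),
    truth = data.frame(peptide_id = character(),
                       generating_protease = character(),
                       p1_position = integer(), stringsAsFactors = FALSE))
  if (n == 0) return(empty)
  with_seed(derive_seed(seed, 211L), {
    pool <- switch(mode,
      "observed-cut" = data.frame(protease = manifest$sites$protease_accession,
                                  substrate = manifest$sites$substrate_accession,
                                  p1_position = manifest$sites$p1_position,
                                  stringsAsFactors = FALSE),
      "matrix-sampled" = {
        p <- manifest$predictable
        if (!is.null(protease)) p <- p[p$protease == protease, , drop = FALSE]
        p
      },
      "random" = NULL)
    peptides <- NULL
    truth <- NULL
    for (i in seq_len(n)) {
      if (mode == "random") {
        acc <- sample(names(kb$proteins), 1L)
        L <- nchar(kb$proteins[[acc]]$sequence)
        start <- sample(seq(6L, L - peptide_length - 6L), 1L)
        gen <- NA_character_
        p1 <- NA_integer_
      } else {
        if (!nrow(pool)) abort("no planted sites available for mode %s", mode)
        row <- pool[sample(nrow(pool), 1L), ]
        acc <- row$substrate
        p1 <- row$p1_position
        start <- p1 + 1L
        gen <- row$protease
      }
      L <- nchar(kb_protein(kb, acc)$sequence)
      end <- min(start + peptide_length - 1L, L - 5L)
      peptides <- rbind(peptides, data.frame(
        peptide_id = sprintf("pep%s%04d", toupper(substr(mode, 1, 1)), i),
        parent_accession = acc, start = start, end = end,
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        peptide_id = peptides$peptide_id[i], generating_protease = gen,
        p1_position = p1, stringsAsFactors = FALSE))
    }
    list(peptides = peptides, truth = truth)
  })
}

#' The worked human co-location example knowledge base
#'
#' Writes a small, fully deterministic bundle holding four human proteins:
#' the matrix metalloproteinase-2 protease (`PR:P08253`) with the serum
#' albumin substrate (`PR:P02768`) — a pair sharing nucleus
#' (`GO:0005634`), extracellular region (`GO:0005576`) and extracellular
#' space (`GO:0005615`) — and the neutrophil elastase protease
#' (`PR:P08246`) with the ABC transporter A6 substrate (`PR:Q8N139`),
#' which share their taxon but no cellular location.  Each protein
#' additionally carries two locations its partner lacks, so the
#' intersections are exercised non-trivially.  Sequences are synthetic
#' (random, fixed seed): only the annotation structure mirrors the real
#' proteins.  An observed cleavage of albumin by MMP-2 with P1' at
#' residue 25 is planted, and MMP-2 carries a usable specificity matrix.
#'
#' @param dir Output directory.
#' @return List with `dir` and the [kb_bundle()].
#' @export
example_human_kb <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(20160604L, {
    accs <- c("PR:P08253", "PR:P02768", "PR:P08246", "PR:Q8N139")
    seqs <- vapply(accs, function(a) random_sequence(60L), "")
    fa <- data.frame(accession = accs, alt_id = NA_character_,
                     description = c("PR:P08253 72 kDa type IV collagenase (synthetic sequence)",
                                     "PR:P02768 Serum albumin (synthetic sequence)",
                                     "PR:P08246 Neutrophil elastase (synthetic sequence)",
                                     "PR:Q8N139 ATP-binding cassette sub-family A member 6 (synthetic sequence)"),
                     sequence = unname(seqs), stringsAsFactors = FALSE)
    locs <- list(
      "PR:P08253" = c("GO:0005634", "GO:0005576", "GO:0005615",
                      "GO:0005737", "GO:0016020"),
      "PR:P02768" = c("GO:0005634", "GO:0005576", "GO:0005615",
                      "GO:0005739", "GO:0005886"),
      "PR:P08246" = c("GO:0005764", "GO:0005737"),
      "PR:Q8N139" = c("GO:0016020", "GO:0005886", "GO:0005739"))
    mf <- list("PR:P08253" = "GO:0004222", "PR:P02768" = character(),
               "PR:P08246" = "GO:0004252", "PR:Q8N139" = "GO:0005215")
    bp <- list("PR:P08253" = "GO:0006508", "PR:P02768" = character(),
               "PR:P08246" = "GO:0006508", "PR:Q8N139" = "GO:0055085")
    ann <- NULL
    for (a in accs) {
      ann <- rbind(ann, data.frame(accession = a, term = "NCBI:9606",
                                   facet = "taxon", stringsAsFactors = FALSE))
      for (t in mf[[a]]) ann <- rbind(ann, data.frame(accession = a, term = t,
                                                      facet = "molecular_function"))
      for (t in bp[[a]]) ann <- rbind(ann, data.frame(accession = a, term = t,
                                                      facet = "biological_process"))
      for (t in locs[[a]]) ann <- rbind(ann, data.frame(accession = a, term = t,
                                                        facet = "cellular_component"))
    }
    p1 <- 24L # the planted albumin cleavage: P1' at residue 25
    sites <- data.frame(substrate_accession = "PR:P02768", p1_position = p1,
                        nonprime_length = 4L,
                        site_sequence = substr1(seqs[["PR:P02768"]], p1 - 3L, p1 + 4L),
                        protease_accession = "PR:P08253",
                        source = "curated-db", stringsAsFactors = FALSE)
    # a usable matrix for MMP-2, concentrated on its planted site residues
    site_res <- residues(sites$site_sequence)
    counts <- t(vapply(seq_len(8L), function(pos)
      as.vector(stats::rmultinom(1, 60L, strength_probs(0.85, site_res[pos]))),
      numeric(20)))
    colnames(counts) <- AA20
    matrices <- list("PR:P08253" = specificity_matrix("PR:P08253", counts, 4L, 60L))

    write_fasta(fa, file.path(dir, "proteins.fasta"))
    write_obo(mini_go_graph(), file.path(dir, "go.obo"))
    write_annotations(ann, file.path(dir, "annotations.tsv"))
    write_taxa(default_taxa(), file.path(dir, "taxa.tsv"))
    write_cleavage_sites(sites, file.path(dir, "cleavage_sites.tsv"))
    write_matrices(matrices, file.path(dir, "matrices.tsv"))
    write_exopeptidase_catalog(setNames(character(), character()),
                               file.path(dir, "exopeptidase_catalog.tsv"))
    list(dir = dir, bundle = kb_bundle_from_dir(dir))
  })
}
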