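test_that("matrix usability follows the 40-cleavage / 10-fold enrichment rule", {
  AA20 <- protcleave:::AA20
  flat40 <- specificity_matrix("PR:A", matrix(2L, 4, 20,
                                              dimnames = list(NULL, AA20)),
                               nonprime = 2L, total = 40L)
  expect_true(matrix_usable(flat40))

  concentrated <- matrix(0L, 4, 20, dimnames = list(NULL, AA20))
  concentrated[, "K"] <- 10L
  m10 <- specificity_matrix("PR:B", concentrated, nonprime = 2L, total = 10L)
  expect_true(matrix_usable(m10)) # frequency 1.0 is 20x the uniform 1/20

  flat10 <- matrix(0L, 4, 20, dimnames = list(NULL, AA20))
  flat10[, 1:10] <- 1L
  m_flat10 <- specificity_matrix("PR:C", flat10, nonprime = 2L, total = 10L)
  expect_false(matrix_usable(m_flat10))
})

test_that("probability transformation is the count/N division, with optional smoothing", {
  counts <- matrix(0L, 1, 20, dimnames = list(NULL, protcleave:::AA20))
  counts[1, "K"] <- 30L
  counts[1, "R"] <- 10L
  m <- specificity_matrix("PR:A", counts, nonprime = 1L, total = 40L)
  pm0 <- to_probabilities(m, pseudocount = 0)
  expect_identical(unname(pm0$probs[1, "K"]), 30 / 40) # exact: 0.75
  expect_identical(unname(pm0$probs[1, "R"]), 0.25)
  expect_identical(unname(pm0$probs[1, "A"]), 0)

  pm1 <- to_probabilities(m, pseudocount = 1)
  expect_equal(unname(pm1$probs[1, "K"]), 31 / 60)
  expect_true(all(pm1$probs > 0))

  onehot <- matrix(0L, 1, 20, dimnames = list(NULL, protcleave:::AA20))
  onehot[1, "W"] <- 40L
  pmh <- to_probabilities(specificity_matrix("PR:B", onehot, 1L, 40L),
                          pseudocount = 0)
  expect_identical(unname(pmh$probs[1, "W"]), 1)
  expect_identical(sum(pmh$probs[1, ] != 0), 1L)
})

test_that("log-likelihood scoring matches hand-computed values", {
  uniform <- probability_matrix(matrix(1 / 20, 8, 20,
                                       dimnames = list(NULL, protcleave:::AA20)),
                                nonprime = 4L)
  w <- window_for("GHIK", "LMNP")
  expect_equal(loglik_score(w, uniform), 0)

  single <- probability_matrix(matrix(c(rep(0, 8), 1, rep(0, 11)), 1, 20,
                                      dimnames = list(NULL, protcleave:::AA20)),
                               nonprime = 1L)
  wk <- window_for("K", "")
  expect_equal(loglik_score(wk, single), log(20), tolerance = 1e-12)

  pm2 <- two_letter_pmatrix()
  expect_equal(loglik_score(window_for("A", "A"), pm2), log(1.5),
               tolerance = 1e-12)

  # zero probabilities must be refused with advice to use a pseudocount
  expect_error(loglik_score(window_for("A", "A"),
                            probability_matrix(rbind(c(A = 1, B = 0),
                                                     c(A = 0, B = 1)),
                                               nonprime = 1L)),
               "pseudocount")
})

test_that("truncated windows are scored over their available positions only", {
  pm <- two_letter_pmatrix()
  w_np_only <- window_for("A", "")
  expect_equal(loglik_score(w_np_only, pm), log(0.75 / 0.5), tolerance = 1e-12)
  w_pr_only <- window_for("", "B")
  expect_equal(loglik_score(w_pr_only, pm), 0, tolerance = 1e-12)
})

test_that("the exact score distribution equals brute-force enumeration", {
  pm2 <- two_letter_pmatrix()
  d <- score_distribution(pm2)
  expect_equal(d$support, c(log(0.5), log(1.5)), tolerance = 1e-9)
  expect_equal(d$mass, c(0.5, 0.5))

  uniform <- probability_matrix(matrix(1 / 20, 6, 20,
                                       dimnames = list(NULL, protcleave:::AA20)),
                                nonprime = 3L)
  du <- score_distribution(uniform)
  expect_equal(du$support, 0)
  expect_equal(du$mass, 1)

  # randomized oracle equivalence, alphabet <= 4 and positions <= 4
  withr::with_seed(42, {
    for (case in 1:8) {
      n_alpha <- sample(2:4, 1)
      n_pos <- sample(2:4, 1)
      pm <- random_pmatrix(n_alpha, n_pos, nonprime = sample(n_pos, 1) - 1L)
      d <- score_distribution(pm)
      oracle <- enumerate_distribution(pm)
      expect_equal(d$support, oracle$support, tolerance = 1e-9)
      expect_equal(d$mass, oracle$mass, tolerance = 1e-12)
      expect_equal(sum(d$mass), 1, tolerance = 1e-9)
      expect_true(all(diff(d$support) > 0))
    }
  })
})

test_that("the Monte-Carlo cross-check agrees with the exact distribution", {
  withr::with_seed(3, {
    pm <- random_pmatrix(4, 3, nonprime = 2L)
  })
  d <- score_distribution(pm)
  draws <- score_distribution_mc(pm, draws = 20000, seed = 11)
  t99_exact <- match_threshold(d, 90)
  emp <- unname(stats::quantile(draws, 0.9, type = 1))
  expect_lt(abs(mean(draws) - sum(d$support * d$mass)), 0.05)
  expect_lt(abs(emp - t99_exact), 0.35)
})

test_that("the match threshold sits at the population percentile, ties to non-match", {
  degenerate <- structure(list(support = 0, mass = 1),
                          class = "score_distribution")
  expect_equal(match_threshold(degenerate), 0)
  sm <- getFromNamespace("score_matches", "protcleave")
  expect_false(sm(0, match_threshold(degenerate)))

  two <- structure(list(support = c(-0.6931, 0.4055), mass = c(0.5, 0.5)),
                   class = "score_distribution")
  expect_equal(match_threshold(two, 99), 0.4055)
  expect_false(sm(0.4055, 0.4055))
  expect_true(sm(0.41, 0.4055))

  withr::with_seed(8, {
    pm <- random_pmatrix(4, 4, nonprime = 2L)
  })
  d <- score_distribution(pm)
  ts <- vapply(c(50, 90, 99, 99.9), match_threshold, 0, dist = d)
  expect_true(all(diff(ts) >= 0)) # non-decreasing in percentile
  expect_error(match_threshold(d, 100), "between 0 and 100")
})

test_that("threshold and percentile rank are mutually consistent", {
  withr::with_seed(13, {
    for (case in 1:5) {
      pm <- random_pmatrix(4, 4, nonprime = 2L)
      d <- score_distribution(pm)
      for (p in c(90, 99, 99.5)) {
        t <- match_threshold(d, p)
        expect_gte(score_percentile(t, d), p)
        below <- d$support[d$support < t - 1e-9]
        if (length(below))
          expect_lt(score_percentile(max(below), d), p)
      }
    }
  })
})

test_that("confidence levels band the percentile rank", {
  withr::with_seed(21, {
    pm <- random_pmatrix(4, 4, nonprime = 2L)
  })
  d <- score_distribution(pm)
  t <- match_threshold(d, 99)
  expect_equal(assign_confidence(min(d$support), d), "none")
  expect_equal(assign_confidence(max(d$support), d), "high")
  # hand-check every band against the rank definition
  for (s in d$support[c(1, length(d$support) %/% 2, length(d$support))]) {
    r <- score_percentile(s, d)
    want <- if (r >= 99.9) "high" else if (r >= 99.5) "medium"
            else if (r >= 99) "low" else "none"
    expect_equal(assign_confidence(s, d), want)
  }
})

test_that("prediction emits only above-threshold matches from usable matrices", {
  gen <- default_gen()
  kb <- gen$kb
  site <- gen$gen$manifest$predictable[1, ]
  pep <- list(peptide_id = "m", parent_accession = site$substrate,
              start = site$p1_position + 1L, end = site$p1_position + 12L)
  w <- reconstruct_termini(kb$proteins[[site$substrate]], pep)$N
  ev <- predict_cleavage(w, pep, kb)
  expect_gte(nrow(ev), 1L)
  expect_equal(ev$protease_accession[1], site$protease)
  expect_equal(ev$confidence[1], "high")
  expect_true(all(ev$percentile >= 99))
  expect_true(all(diff(ev$percentile) <= 0)) # sorted by rank

  # a uniform probability matrix never exceeds its own (degenerate) threshold
  go <- tiny_go()
  prx <- protein_record("PR:U", "ACDEFGHIKL", functions = "GO:0008233")
  sub <- protein_record("PR:V", TOY_SEQ)
  flat <- specificity_matrix("PR:U", matrix(2L, 8, 20,
                                            dimnames = list(NULL, protcleave:::AA20)),
                             nonprime = 4L, total = 40L)
  kbu <- knowledge_base(list(prx, sub), go, matrices = list("PR:U" = flat))
  pep2 <- list(peptide_id = "u", parent_accession = "PR:V", start = 10L, end = 18L)
  w2 <- reconstruct_termini(sub, pep2)$N
  expect_equal(nrow(predict_cleavage(w2, pep2, kbu)), 0L)

  # an unusable matrix is excluded even if the window would score high
  weak <- specificity_matrix("PR:U", matrix(1L, 8, 20,
                                            dimnames = list(NULL, protcleave:::AA20)),
                             nonprime = 4L, total = 20L)
  kbw <- knowledge_base(list(prx, sub), go, matrices = list("PR:U" = weak))
  expect_equal(nrow(predict_cleavage(w2, pep2, kbw)), 0L)
})

test_that("peptides sampled from a matrix are re-predicted with that matrix first", {
  gen <- default_gen()
  kb <- gen$kb
  pepset <- generate_peptides(kb, gen$gen$manifest, "matrix-sampled",
                              n = 25, seed = 31)
  ok <- 0L
  for (i in seq_len(nrow(pepset$peptides))) {
    pep <- pepset$peptides[i, ]
    w <- reconstruct_termini(kb$proteins[[pep$parent_accession]], pep)$N
    ev <- predict_cleavage(w, pep, kb)
    if (nrow(ev) && ev$protease_accession[1] == pepset$truth$generating_protease[i])
      ok <- ok + 1L
  }
  expect_gte(ok / nrow(pepset$peptides), 0.9)
})

test_that("exopeptidase rescue recovers a shifted strong site and respects the catalog", {
  gen <- default_gen()
  kb <- gen$kb
  site <- gen$gen$manifest$predictable[2, ]
  pep <- list(peptide_id = "r", parent_accession = site$substrate,
              start = site$p1_position + 2L, end = site$p1_position + 16L)
  w <- reconstruct_termini(kb$proteins[[site$substrate]], pep)$N
  ev <- exopeptidase_rescue(w, pep, kb)
  expect_gte(nrow(ev), 2L)
  expect_true(all(ev$rescue))
  endo <- ev[ev$protease_accession == site$protease, ]
  expect_equal(nrow(endo), 1L)
  expect_equal(endo$p1_position, site$p1_position) # shifted bond recovered
  exo <- ev[ev$protease_accession == "PR:EXOA01", ]
  expect_equal(exo$partner_event_id, endo$event_id)

  kb2 <- kb
  kb2$exopeptidase_catalog <- setNames(character(), character())
  expect_equal(nrow(exopeptidase_rescue(w, pep, kb2)), 0L)

  # C-terminal rescue requires a carboxypeptidase, not an aminopeptidase
  kb3 <- kb
  kb3$exopeptidase_catalog <- kb$exopeptidase_catalog[
    kb$exopeptidase_catalog == "aminopeptidase"]
  pepc <- list(peptide_id = "rc", parent_accession = site$substrate,
               start = site$p1_position - 16L, end = site$p1_position - 2L)
  wc <- reconstruct_termini(kb$proteins[[site$substrate]], pepc)$C
  expect_equal(nrow(exopeptidase_rescue(wc, pepc, kb3)), 0L)
})
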