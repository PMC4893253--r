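# Shared fixtures, all built in code at test time.

TOY_SEQ <- "ACDEFGHIKLMNPQRSTVWYACDEFG" # 26 aa

toy_protein <- function() protein_record("PR:TOY", TOY_SEQ)

tiny_go <- function() {
  go_graph(
    id = c("GO:0003674", "GO:0008233", "GO:0008238", "GO:0004177",
           "GO:0008150", "GO:0006508", "GO:0005575", "GO:0005634"),
    name = c("molecular_function", "peptidase activity",
             "exopeptidase activity", "aminopeptidase activity",
             "biological_process", "proteolysis", "cellular_component",
             "nucleus"),
    namespace = c(rep("molecular_function", 4),
                  rep("biological_process", 2),
                  rep("cellular_component", 2)),
    parents = list(character(), "GO:0003674", "GO:0008233", "GO:0008238",
                   character(), "GO:0008150", character(), "GO:0005575"))
}

# Memoized generated bundles: expensive fixtures shared across test files.
fixture_env <- new.env(parent = emptyenv())

cached_gen_kb <- function(key, ...) {
  if (is.null(fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("kbgen_", key))
    gen <- generate_kb(dir, ...)
    fixture_env[[key]] <- list(gen = gen, kb = build_kb(gen$bundle))
  }
  fixture_env[[key]]
}

default_gen <- function() cached_gen_kb("default", seed = 7L)

example_kb <- function() {
  if (is.null(fixture_env$example)) {
    ex <- example_human_kb(file.path(tempdir(), "kb_example"))
    fixture_env$example <- list(gen = ex, kb = build_kb(ex$bundle))
  }
  fixture_env$example
}

# A 2-letter-alphabet probability matrix: position P1 prefers A (0.75),
# position P1' is indifferent; background uniform 0.5.
two_letter_pmatrix <- function() {
  probs <- rbind(c(A = 0.75, B = 0.25), c(A = 0.5, B = 0.5))
  probability_matrix(probs, nonprime = 1L)
}

window_for <- function(nonprime, prime, terminus = "N", p1 = 10L) {
  structure(list(terminus = terminus, p1_position = as.integer(p1),
                 nonprime = nonprime, prime = prime,
                 truncated_nonprime = FALSE, truncated_prime = FALSE,
                 at_protein_terminus = FALSE),
            class = "terminus_window")
}

# Independent oracle: score distribution by brute-force enumeration of
# every sequence over the matrix alphabet at the given positions.
enumerate_distribution <- function(pmatrix, labels = rownames(pmatrix$probs)) {
  alpha <- colnames(pmatrix$probs)
  grids <- rep(list(alpha), length(labels))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  scores <- apply(combos, 1, function(res)
    sum(log(pmatrix$probs[cbind(labels, unname(res))] /
              pmatrix$background[unname(res)])))
  scores <- sort(scores)
  grp <- cumsum(c(TRUE, diff(scores) > 1e-9))
  support <- as.vector(tapply(scores, grp, mean))
  mass <- as.vector(tapply(scores, grp, length)) / length(scores)
  list(support = support, mass = mass)
}

# Brute-force observed matcher: detailed criteria applied to every record.
brute_force_observed <- function(window, peptide, kb) {
  cs <- kb$cleavage_sites
  parent <- kb$proteins[[peptide$parent_accession]]
  which(cs$substrate_accession == parent$accession &
          cs$p1_position == window$p1_position)
}

random_pmatrix <- function(n_alpha, n_pos, nonprime) {
  probs <- t(vapply(seq_len(n_pos), function(i) {
    p <- stats::runif(n_alpha, 0.05, 1)
    p / sum(p)
  }, numeric(n_alpha)))
  colnames(probs) <- LETTERS[seq_len(n_alpha)]
  probability_matrix(probs, nonprime = nonprime)
}
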