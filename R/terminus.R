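#' Extract a peptide sequence from its parent protein
#'
#' Coordinates are 1-based and inclusive at both ends (UniProt convention):
#' `start` is the first residue of the peptide (P1' of the N-terminal
#' cleavage), `end` the last (P1 of the C-terminal cleavage).
#'
#' @param protein A [protein_record()].
#' @param start,end Integer positions, `1 <= start <= end <= length`.
#' @return The peptide residue string of length `end - start + 1`.
#' @export
extract_peptide_sequence <- function(protein, start, end) {
  L <- nchar(protein$sequence)
  if (!is_count(start) || !is_count(end))
    abort("start and end must be single integers")
  if (start < 1 || end > L)
    abort("coordinates %d..%d outside sequence 1..%d of %s",
          start, end, L, protein$accession)
  if (start > end) abort("start (%d) > end (%d)", start, end)
  substr1(protein$sequence, start, end)
}

# Window around an arbitrary scissile bond P1|P1' at parent position p1.
bond_window <- function(protein, p1, flank, terminus) {
  L <- nchar(protein$sequence)
  at_term <- (p1 < 1L) || (p1 >= L)
  np_from <- max(1L, p1 - flank + 1L)
  np <- if (p1 >= 1L) substr1(protein$sequence, np_from, p1) else ""
  pr_to <- min(L, p1 + flank)
  pr <- if (p1 < L) substr1(protein$sequence, p1 + 1L, pr_to) else ""
  structure(list(terminus = terminus, p1_position = as.integer(p1),
                 nonprime = np, prime = pr,
                 truncated_nonprime = p1 - flank + 1L < 1L,
                 truncated_prime = p1 + flank > L,
                 at_protein_terminus = at_term),
            class = "terminus_window")
}

#' @export
print.terminus_window <- function(x, ...) {
  cat(sprintf("%s-terminus window: %s | %s (P1 at %d%s%s)\n", x$terminus,
              x$nonprime, x$prime, x$p1_position,
              if (x$truncated_nonprime || x$truncated_prime) ", truncated" else "",
              if (x$at_protein_terminus) ", protein terminus" else ""))
  invisible(x)
}

#' Reconstruct the N- and C-terminal cleavage-site windows of a peptide
#'
#' Given a peptide's coordinates on its parent protein, rebuilds the
#' residue windows around the two candidate scissile bonds: for the N
#' terminus the bond between `start - 1` (P1) and `start` (P1'), for the C
#' terminus the bond between `end` (P1) and `end + 1` (P1').  Non-prime
#' residues lie toward the substrate's N terminus (written Pn..P1
#' left-to-right toward the bond), prime residues toward the C terminus
#' (P1'..Pn').  With the default flank of 4 each window spans eight
#' residues, or fewer when the bond is close to the beginning or end of
#' the protein's sequence; the affected side is then flagged truncated.
#' A peptide starting at residue 1 (or ending at the last residue) has no
#' scissile bond at that terminus: the window is flagged
#' `at_protein_terminus` and carries an empty non-prime (resp. prime)
#' side.
#'
#' @param protein A [protein_record()].
#' @param peptide List or one-row data.frame with `peptide_id`, `start`,
#'   `end` (1-based inclusive).
#' @param flank Residues per side of the bond, 1..4 (default 4, matching
#'   P4..P4' specificity matrices).
#' @return List with elements `N` and `C`, each a `terminus_window`.
#' @examples
#' p <- protein_record("PR:TOY", "ACDEFGHIKLMNPQRSTVWYACDEFG")
#' reconstruct_termini(p, list(peptide_id = "pep1", start = 10, end = 18))
#' @export
reconstruct_termini <- function(protein, peptide, flank = 4L) {
  if (!is_count(flank) || flank < 1 || flank > 4)
    abort("flank must be an integer in 1..4")
  start <- as.integer(peptide$start)
  end <- as.integer(peptide$end)
  extract_peptide_sequence(protein, start, end) # validates coordinates
  list(N = bond_window(protein, start - 1L, as.integer(flank), "N"),
       C = bond_window(protein, end, as.integer(flank), "C"))
}
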