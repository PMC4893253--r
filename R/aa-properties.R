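#' Biochemical properties of the 20 standard amino acids
#'
#' Returns the packaged property table used for the amino-acid competency
#' query and for reasoning about residue interchangeability at cleavage-site
#' positions.  Three facets are recorded per residue: electric charge
#' (positive / negative / uncharged), polarity (polar / nonpolar) and a
#' side-chain structural class (aliphatic, aromatic, sulfur-containing,
#' hydroxylic, amidic, basic, acidic, cyclic).
#'
#' @return A data.frame with one row per residue and columns `residue`,
#'   `charge`, `polarity`, `side_chain_class`.
#' @examples
#' props <- amino_acid_properties()
#' props[props$residue == "D", ]
#' @export
amino_acid_properties <- function() {
  df <- data.frame(
    residue = AA20,
    charge = c(
      A = "uncharged", C = "uncharged", D = "negative",  E = "negative",
      F = "uncharged", G = "uncharged", H = "positive",  I = "uncharged",
      K = "positive",  L = "uncharged", M = "uncharged", N = "uncharged",
      P = "uncharged", Q = "uncharged", R = "positive",  S = "uncharged",
      T = "uncharged", V = "uncharged", W = "uncharged", Y = "uncharged"
    )[AA20],
    polarity = c(
      A = "nonpolar", C = "polar",    D = "polar",    E = "polar",
      F = "nonpolar", G = "nonpolar", H = "polar",    I = "nonpolar",
      K = "polar",    L = "nonpolar", M = "nonpolar", N = "polar",
      P = "nonpolar", Q = "polar",    R = "polar",    S = "polar",
      T = "polar",    V = "nonpolar", W = "nonpolar", Y = "polar"
    )[AA20],
    side_chain_class = c(
      A = "aliphatic", C = "sulfur-containing", D = "acidic",
      E = "acidic",    F = "aromatic",          G = "aliphatic",
      H = "basic",     I = "aliphatic",         K = "basic",
      L = "aliphatic", M = "sulfur-containing", N = "amidic",
      P = "cyclic",    Q = "amidic",            R = "basic",
      S = "hydroxylic", T = "hydroxylic",       V = "aliphatic",
      W = "aromatic",  Y = "aromatic"
    )[AA20],
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

#' Look up the biochemical properties of one residue
#'
#' Competency query over the knowledge base's amino-acid property table:
#' given a one-letter residue code, return its charge, polarity and
#' side-chain class.
#'
#' @param kb A knowledge base built with [knowledge_base()] or [build_kb()].
#' @param residue A single one-letter amino-acid code.
#' @return One-row data.frame with the residue's property values.
#' @seealso [interchangeable()] for residues sharing a property value.
#' @export
cq_aa_properties <- function(kb, residue) {
  stopifnot(inherits(kb, "cleavage_kb"))
  props <- kb$aa_properties
  if (!(is.character(residue) && length(residue) == 1L && residue %in% props$residue))
    abort("unknown residue code '%s' (expected one of %s)",
          as.character(residue)[1], paste(props$residue, collapse = ""))
  props[props$residue == residue, , drop = FALSE]
}

#' Residues interchangeable with a query residue under one property facet
#'
#' Two residues are taken as interchangeable at a cleavage-site position,
#' with respect to a facet, when they share that facet's value (for example
#' D and E both carry a negative charge).  The returned set always contains
#' the query residue itself.
#'
#' @inheritParams cq_aa_properties
#' @param facet One of `"charge"`, `"polarity"`, `"side_chain_class"`.
#' @return Character vector of residue codes, sorted.
#' @export
interchangeable <- function(kb, residue, facet = c("charge", "polarity", "side_chain_class")) {
  facet <- match.arg(facet)
  row <- cq_aa_properties(kb, residue)
  props <- kb$aa_properties
  sort(props$residue[props[[facet]] == row[[facet]]])
}
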