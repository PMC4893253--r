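# Shared internal helpers.

# The 20 standard amino acids, one-letter codes, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# substr with 1-based inclusive coordinates; empty string when from > to.
substr1 <- function(x, from, to) {
  if (from > to) return("")
  substr(x, from, to)
}

# Split a residue string into single characters.
residues <- function(x) if (nzchar(x)) strsplit(x, "", fixed = TRUE)[[1]] else character()

# Check a residue string against the 20-letter alphabet; returns the index of
# the first offending character or 0L.
first_illegal_residue <- function(x) {
  ch <- residues(x)
  bad <- which(!ch %in% AA20)
  if (length(bad)) bad[1] else 0L
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x)
}

# Deterministic seed derivation: offsets keep sub-streams independent while
# staying inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
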