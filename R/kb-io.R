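# Readers and writers for the on-disk knowledge-base formats.  All
# tabular files are plain TSV; positions are 1-based inclusive throughout,
# matching the internal representation (no conversions anywhere).

#' Describe the source files of a knowledge base
#'
#' @param fasta,obo,annotations,taxa,cleavage_sites,matrices,exopeptidase_catalog
#'   Paths to the respective files.
#' @param aa_properties Optional path to an amino-acid property TSV;
#'   `NULL` uses the packaged table.
#' @return Object of class `kb_bundle` (a validated list of paths).
#' @export
kb_bundle <- function(fasta, obo, annotations, taxa, cleavage_sites,
                      matrices, exopeptidase_catalog, aa_properties = NULL) {
  paths <- list(fasta = fasta, obo = obo, annotations = annotations,
                taxa = taxa, cleavage_sites = cleavage_sites,
                matrices = matrices,
                exopeptidase_catalog = exopeptidase_catalog,
                aa_properties = aa_properties)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (is.null(p)) next
    if (!file.exists(p)) abort("%s file not readable: %s", nm, p)
  }
  structure(paths, class = "kb_bundle")
}

#' Locate a knowledge-base bundle by directory convention
#'
#' Expects the standard file names `proteins.fasta`, `go.obo`,
#' `annotations.tsv`, `taxa.tsv`, `cleavage_sites.tsv`, `matrices.tsv`,
#' `exopeptidase_catalog.tsv` (plus optional `aa_properties.tsv`).
#'
#' @param dir Knowledge-base directory.
#' @return A [kb_bundle()].
#' @export
kb_bundle_from_dir <- function(dir) {
  aa <- file.path(dir, "aa_properties.tsv")
  kb_bundle(fasta = file.path(dir, "proteins.fasta"),
            obo = file.path(dir, "go.obo"),
            annotations = file.path(dir, "annotations.tsv"),
            taxa = file.path(dir, "taxa.tsv"),
            cleavage_sites = file.path(dir, "cleavage_sites.tsv"),
            matrices = file.path(dir, "matrices.tsv"),
            exopeptidase_catalog = file.path(dir, "exopeptidase_catalog.tsv"),
            aa_properties = if (file.exists(aa)) aa else NULL)
}

#' Read protein sequences from FASTA
#'
#' Headers are parsed by their first whitespace-delimited token; the
#' UniProt `db|AC|ID` convention is recognised, in which case the AC
#' becomes the accession and the ID an alternative identifier.  Sequences
#' are upper-cased and validated against the 20-letter alphabet:
#' ambiguity or non-standard codes (B, J, O, U, X, Z) are rejected with
#' the offending position reported.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `alt_id`, `description`,
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  empty <- data.frame(accession = character(), alt_id = character(),
                      description = character(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) {
    warnf("FASTA file '%s' is empty", path)
    return(empty)
  }
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) {
    warnf("FASTA file '%s' contains no records", path)
    return(empty)
  }
  headers <- names(set)
  seqs <- toupper(as.character(set))
  first_tok <- sub("\\s.*$", "", headers)
  acc <- first_tok
  alt <- rep(NA_character_, length(acc))
  bar <- grepl("^[^|]+\\|[^|]+\\|[^|]+$", first_tok)
  parts <- strsplit(first_tok[bar], "|", fixed = TRUE)
  acc[bar] <- vapply(parts, `[[`, "", 2L)
  alt[bar] <- vapply(parts, `[[`, "", 3L)
  if (anyDuplicated(acc))
    abort("duplicate accession(s) in FASTA: %s",
          paste(unique(acc[duplicated(acc)]), collapse = ", "))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) abort("empty sequence record for %s", acc[i])
    bad <- first_illegal_residue(seqs[i])
    if (bad > 0L)
      abort("record %s: illegal residue '%s' at position %d",
            acc[i], substr(seqs[i], bad, bad), bad)
  }
  data.frame(accession = acc, alt_id = alt, description = unname(headers),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

write_fasta <- function(df, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(paste0(">", df$description[i]), con)
    s <- df$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

read_tsv_checked <- function(path, required, what, optional = character()) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^!", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(NULL)
  # sentinel preserves trailing empty fields, which strsplit would drop
  fields <- lapply(strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE),
                   function(x) { x[length(x)] <- sub("\x01$", "", x[length(x)]); x })
  header <- fields[[1]]
  miss <- setdiff(required, header)
  if (length(miss))
    abort("%s file '%s': missing column(s) %s", what, path,
          paste(miss, collapse = ", "))
  extra <- setdiff(header, c(required, optional))
  if (length(extra))
    warnf("%s file '%s': ignoring unknown column(s) %s", what, path,
          paste(extra, collapse = ", "))
  rows <- fields[-1]
  lineno <- lineno[-1]
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    abort("%s file '%s': malformed row at line %d (%d fields, expected %d)",
          what, path, lineno[bad[1]], lengths(rows)[bad[1]], length(header))
  if (!length(rows)) {
    df <- as.data.frame(setNames(rep(list(character()), length(header)), header),
                        stringsAsFactors = FALSE)
  } else {
    mat <- do.call(rbind, rows)
    colnames(mat) <- header
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
  }
  df <- df[required]
  attr(df, "lineno") <- lineno
  df
}

#' Read a protein annotation table
#'
#' GAF-like TSV with columns `accession`, `term`, `facet` and optional
#' `!`-prefixed comment lines.  `facet` is one of the three GO namespaces
#' (in which case `term` must exist in the graph under that namespace),
#' `taxon`, or `gene`.
#'
#' @param path Annotation TSV path.
#' @param go Optional [go_graph()]; when supplied, GO rows are validated
#'   against it.
#' @return data.frame with columns `accession`, `term`, `facet`.
#' @export
read_annotations <- function(path, go = NULL) {
  df <- read_tsv_checked(path, c("accession", "term", "facet"), "annotation")
  if (is.null(df))
    return(data.frame(accession = character(), term = character(),
                      facet = character(), stringsAsFactors = FALSE))
  ok <- c("molecular_function", "biological_process", "cellular_component",
          "taxon", "gene")
  bad <- setdiff(unique(df$facet), ok)
  if (length(bad))
    abort("annotation file '%s': unknown facet(s) %s", path,
          paste(bad, collapse = ", "))
  if (!is.null(go)) {
    go_rows <- df$facet %in% ok[1:3]
    for (i in which(go_rows)) {
      if (!go_has_term(go, df$term[i]))
        abort("annotation file '%s': unknown GO term %s (for %s)", path,
              df$term[i], df$accession[i])
      if (go_namespace(go, df$term[i]) != df$facet[i])
        abort("annotation file '%s': term %s is in namespace %s, row says %s",
              path, df$term[i], go_namespace(go, df$term[i]), df$facet[i])
    }
  }
  df
}

write_annotations <- function(df, path) {
  write_plain_tsv(df[c("accession", "term", "facet")], path)
}

write_plain_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Read observed cleavage-site records
#'
#' TSV with columns `substrate_acc`, `p1_pos`, `nonprime_len`, `site_seq`,
#' `protease_acc`, `source` (one of `curated-db`, `sequence-db`,
#' `literature`).  Cross-checks against sequences are deferred to
#' [build_kb()].
#'
#' @param path Cleavage-site TSV path.
#' @return data.frame of cleavage-site records (see [knowledge_base()]).
#' @export
read_cleavage_sites <- function(path) {
  df <- read_tsv_checked(path, c("substrate_acc", "p1_pos", "nonprime_len",
                                 "site_seq", "protease_acc", "source"),
                         "cleavage-site")
  if (is.null(df)) return(empty_cleavage_sites())
  lineno <- attr(df, "lineno")
  p1 <- suppressWarnings(as.integer(df$p1_pos))
  k <- suppressWarnings(as.integer(df$nonprime_len))
  bad <- which(is.na(p1) | is.na(k) | k < 1 | p1 < 1 |
                 k > nchar(df$site_seq))
  if (length(bad))
    abort("cleavage-site file '%s': malformed row at line %d", path,
          lineno[bad[1]])
  src_ok <- c("curated-db", "sequence-db", "literature")
  bad <- which(!df$source %in% src_ok)
  if (length(bad))
    abort("cleavage-site file '%s': unknown source '%s' at line %d", path,
          df$source[bad[1]], lineno[bad[1]])
  data.frame(substrate_accession = df$substrate_acc, p1_position = p1,
             nonprime_length = k, site_sequence = toupper(df$site_seq),
             protease_accession = df$protease_acc, source = df$source,
             stringsAsFactors = FALSE)
}

write_cleavage_sites <- function(cs, path) {
  write_plain_tsv(data.frame(substrate_acc = cs$substrate_accession,
                             p1_pos = cs$p1_position,
                             nonprime_len = cs$nonprime_length,
                             site_seq = cs$site_sequence,
                             protease_acc = cs$protease_accession,
                             source = cs$source, stringsAsFactors = FALSE),
                  path)
}

#' Read specificity matrices
#'
#' Each matrix block starts with a header line
#' `#protease=<acc> nonprime=<k> total=<N>`, followed by a column-label
#' line (`pos` then residue codes) and one row per position, labelled
#' `P<k>..P1, P1'..P<m>'`, holding the occurrence counts.  The explicit
#' non-prime count makes windows shorter than 8 residues align
#' unambiguously.  `read_matrices()` reads a multi-block file into a
#' named list; `read_matrix()` expects exactly one block.
#'
#' @param path Matrix TSV path.
#' @return Named list of [specificity_matrix()] (for `read_matrices`) or a
#'   single matrix (for `read_matrix`).
#' @export
read_matrices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^#protease=", lines)
  if (!length(starts)) {
    if (length(lines)) abort("matrix file '%s': no '#protease=' header", path)
    return(list())
  }
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    hdr <- block[1]
    get_field <- function(name) {
      m <- regmatches(hdr, regexec(paste0(name, "=([^ \t]+)"), hdr))[[1]]
      if (length(m) < 2) abort("matrix file '%s': header missing %s=", path, name)
      m[2]
    }
    acc <- get_field("protease")
    k <- as.integer(get_field("nonprime"))
    total <- as.integer(get_field("total"))
    if (length(block) < 3) abort("matrix file '%s': truncated block for %s", path, acc)
    cols <- strsplit(block[2], "\t", fixed = TRUE)[[1]]
    if (cols[1] != "pos")
      abort("matrix file '%s': expected 'pos' column header for %s", path, acc)
    res_cols <- cols[-1]
    rows <- strsplit(block[-(1:2)], "\t", fixed = TRUE)
    if (any(lengths(rows) != length(cols)))
      abort("matrix file '%s': ragged row in block for %s", path, acc)
    labels <- vapply(rows, `[[`, "", 1L)
    counts <- do.call(rbind, lapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(r[-1]))
      if (anyNA(v)) abort("matrix file '%s': non-numeric count in block for %s",
                          path, acc)
      v
    }))
    colnames(counts) <- res_cols
    m <- length(labels) - k
    expected <- position_labels(k, m)
    if (m < 0 || !identical(labels, expected))
      abort(paste0("matrix file '%s': block for %s declares nonprime=%d but ",
                   "has row labels %s (expected %s)"), path, acc, k,
            paste(labels, collapse = ","), paste(expected, collapse = ","))
    out[[acc]] <- specificity_matrix(acc, counts, k, total)
  }
  out
}

#' @rdname read_matrices
#' @export
read_matrix <- function(path) {
  ms <- read_matrices(path)
  if (length(ms) != 1L)
    abort("matrix file '%s': expected exactly one matrix block, found %d",
          path, length(ms))
  ms[[1]]
}

write_matrices <- function(matrices, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (acc in names(matrices)) {
    m <- matrices[[acc]]
    writeLines(sprintf("#protease=%s nonprime=%d total=%d", acc, m$nonprime,
                       m$total), con)
    writeLines(paste(c("pos", colnames(m$counts)), collapse = "\t"), con)
    for (i in seq_len(nrow(m$counts)))
      writeLines(paste(c(rownames(m$counts)[i], format(m$counts[i, ],
                                                       trim = TRUE,
                                                       scientific = FALSE)),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read the taxon table
#'
#' TSV with columns `taxon_id`, `name`, `parent_id` (empty for roots).
#' Lineages (species upward) are derived by walking `parent_id`.
#'
#' @param path Taxon TSV path.
#' @return Named list of taxon nodes.
#' @export
read_taxa <- function(path) {
  df <- read_tsv_checked(path, c("taxon_id", "name", "parent_id"), "taxon")
  if (is.null(df)) return(list())
  if (anyDuplicated(df$taxon_id))
    abort("taxon file '%s': duplicate taxon id", path)
  parent <- setNames(df$parent_id, df$taxon_id)
  out <- list()
  for (i in seq_len(nrow(df))) {
    lineage <- character()
    cur <- parent[[df$taxon_id[i]]]
    while (!is.na(cur) && nzchar(cur)) {
      if (cur %in% lineage || length(lineage) > nrow(df))
        abort("taxon file '%s': cycle in parent links at %s", path, cur)
      if (!cur %in% df$taxon_id)
        abort("taxon file '%s': parent %s not defined", path, cur)
      lineage <- c(lineage, cur)
      cur <- parent[[cur]]
    }
    out[[df$taxon_id[i]]] <- taxon_node(df$taxon_id[i], df$name[i], lineage)
  }
  out
}

write_taxa <- function(taxa, path) {
  df <- data.frame(
    taxon_id = vapply(taxa, `[[`, "", "taxon_id"),
    name = vapply(taxa, `[[`, "", "name"),
    parent_id = vapply(taxa, function(t)
      if (length(t$lineage)) t$lineage[1] else "", ""),
    stringsAsFactors = FALSE)
  write_plain_tsv(df[order(df$taxon_id), ], path)
}

#' Read the exopeptidase catalog
#'
#' TSV with columns `protease_acc`, `type` (`aminopeptidase` or
#' `carboxypeptidase`).
#'
#' @param path Catalog TSV path.
#' @return Named character vector mapping accessions to type.
#' @export
read_exopeptidase_catalog <- function(path) {
  df <- read_tsv_checked(path, c("protease_acc", "type"), "exopeptidase-catalog")
  if (is.null(df)) return(setNames(character(), character()))
  bad <- setdiff(unique(df$type), c("aminopeptidase", "carboxypeptidase"))
  if (length(bad))
    abort("exopeptidase catalog '%s': unknown type(s) %s", path,
          paste(bad, collapse = ", "))
  setNames(df$type, df$protease_acc)
}

write_exopeptidase_catalog <- function(catalog, path) {
  write_plain_tsv(data.frame(protease_acc = names(catalog),
                             type = unname(catalog),
                             stringsAsFactors = FALSE), path)
}

read_aa_properties <- function(path) {
  df <- read_tsv_checked(path, c("residue", "charge", "polarity",
                                 "side_chain_class"), "amino-acid property")
  if (is.null(df)) abort("amino-acid property file '%s' is empty", path)
  attr(df, "lineno") <- NULL
  df
}

#' Read a peptide input table
#'
#' TSV with columns `peptide_id`, `accession`, `start`, `end`: the peptide
#' identifier, the parent protein's accession or alternative id, and the
#' peptide's 1-based inclusive coordinates on the parent (start = P1' of
#' the N-terminal cleavage, end = P1 of the C-terminal cleavage).
#'
#' @param path Peptide TSV path.
#' @return data.frame with columns `peptide_id`, `parent_accession`,
#'   `start`, `end`.
#' @export
read_peptides <- function(path) {
  df <- read_tsv_checked(path, c("peptide_id", "accession", "start", "end"),
                         "peptide")
  if (is.null(df))
    return(data.frame(peptide_id = character(), parent_accession = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  lineno <- attr(df, "lineno")
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(start) | is.na(end) | start < 1 | start > end)
  if (length(bad))
    abort("peptide file '%s': invalid coordinates at line %d", path,
          lineno[bad[1]])
  data.frame(peptide_id = df$peptide_id, parent_accession = df$accession,
             start = start, end = end, stringsAsFactors = FALSE)
}

write_peptides <- function(df, path) {
  write_plain_tsv(data.frame(peptide_id = df$peptide_id,
                             accession = df$parent_accession,
                             start = df$start, end = df$end,
                             stringsAsFactors = FALSE), path)
}

#' Build a knowledge base from a source bundle
#'
#' Reads every file of a [kb_bundle()], assembles protein records (taxon
#' and gene assignments come from `taxon` / `gene` facet rows of the
#' annotation table) and validates all cross-references through
#' [knowledge_base()]; any violation aborts with a report listing every
#' failure.  The result is deterministic: the same bundle yields an
#' identical knowledge base regardless of file row order.
#'
#' @param bundle A [kb_bundle()] (or a directory accepted by
#'   [kb_bundle_from_dir()]).
#' @return A `cleavage_kb`.
#' @export
build_kb <- function(bundle) {
  if (is.character(bundle)) bundle <- kb_bundle_from_dir(bundle)
  stopifnot(inherits(bundle, "kb_bundle"))
  go <- read_obo(bundle$obo)
  fa <- read_fasta(bundle$fasta)
  ann <- read_annotations(bundle$annotations, go = go)
  taxa <- read_taxa(bundle$taxa)
  cs <- read_cleavage_sites(bundle$cleavage_sites)
  matrices <- read_matrices(bundle$matrices)
  catalog <- read_exopeptidase_catalog(bundle$exopeptidase_catalog)
  aa <- if (!is.null(bundle$aa_properties))
    read_aa_properties(bundle$aa_properties) else amino_acid_properties()
  proteins <- lapply(seq_len(nrow(fa)), function(i) {
    acc <- fa$accession[i]
    rows <- ann[ann$accession == acc, , drop = FALSE]
    pick <- function(facet) sort(rows$term[rows$facet == facet])
    tax <- rows$term[rows$facet == "taxon"]
    gene <- rows$term[rows$facet == "gene"]
    protein_record(accession = acc, sequence = fa$sequence[i],
                   label = fa$description[i],
                   alt_ids = if (is.na(fa$alt_id[i])) character() else fa$alt_id[i],
                   taxon_id = if (length(tax)) tax[1] else NA_character_,
                   gene_id = if (length(gene)) gene[1] else NA_character_,
                   functions = pick("molecular_function"),
                   processes = pick("biological_process"),
                   locations = pick("cellular_component"))
  })
  orphans <- setdiff(unique(ann$accession), fa$accession)
  if (length(orphans))
    warnf("annotations for accession(s) absent from FASTA ignored: %s",
          paste(orphans, collapse = ", "))
  knowledge_base(proteins = proteins, go = go, taxa = taxa,
                 cleavage_sites = cs, matrices = matrices,
                 aa_properties = aa, exopeptidase_catalog = catalog)
}

#' Write proteolysis events to a results TSV
#'
#' One row per event with all event fields plus the validation columns
#' (`taxon_match`, `shared_locations`, `verdict`), which are computed on
#' the fly when absent.  Numeric scores are serialized at full precision;
#' re-reading with [read_events()] restores the table.
#'
#' @param events Event data.frame (validated or not).
#' @param path Output TSV path.
#' @param kb Optional `cleavage_kb`, required when validation columns must
#'   be computed.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, kb = NULL) {
  if (!"verdict" %in% names(events)) {
    if (!is.null(kb)) {
      events <- validate_events(kb, events)
    } else {
      events$taxon_match <- rep(NA, nrow(events))
      events$shared_locations <- rep("", nrow(events))
      events$verdict <- rep("unevaluable", nrow(events))
    }
  }
  num <- vapply(events, is.numeric, TRUE) & !vapply(events, is.integer, TRUE)
  for (cl in names(events)[num])
    events[[cl]] <- ifelse(is.na(events[[cl]]), "",
                           sprintf("%.17g", events[[cl]]))
  events$taxon_match <- ifelse(is.na(events$taxon_match), "",
                               as.integer(events$taxon_match))
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read back a results TSV written by [write_events()]
#'
#' @param path Results TSV path.
#' @return Event data.frame including validation columns.
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = NULL)
  if (!nrow(df)) {
    out <- empty_events()
    out$taxon_match <- logical()
    out$shared_locations <- character()
    out$verdict <- character()
    return(out)
  }
  df$p1_position <- as.integer(df$p1_position)
  df$score <- suppressWarnings(as.numeric(ifelse(df$score == "", NA, df$score)))
  df$percentile <- suppressWarnings(as.numeric(ifelse(df$percentile == "", NA,
                                                      df$percentile)))
  df$rescue <- df$rescue %in% c("TRUE", "1")
  df$partner_event_id <- ifelse(df$partner_event_id == "", NA_character_,
                                df$partner_event_id)
  if ("taxon_match" %in% names(df))
    df$taxon_match <- ifelse(df$taxon_match == "", NA, df$taxon_match == "1")
  df
}
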