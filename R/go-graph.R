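#' A minimal Gene Ontology graph
#'
#' In-memory GO subset holding term ids, names, namespaces and `is_a`
#' parents.  Only `is_a` edges are kept: the protease classification
#' queries traverse the molecular-function hierarchy and never need
#' `part_of` or regulatory relations.
#'
#' @param id Character vector of term ids (e.g. `"GO:0008233"`).
#' @param name Character vector of term names.
#' @param namespace Character vector, each one of `"molecular_function"`,
#'   `"biological_process"`, `"cellular_component"`.
#' @param parents List of character vectors of `is_a` parent ids (one
#'   element per term; `character()` for roots).
#' @return An object of class `go_graph`.
#' @export
go_graph <- function(id, name, namespace, parents) {
  stopifnot(length(id) == length(name), length(id) == length(namespace),
            length(id) == length(parents))
  if (anyDuplicated(id)) abort("duplicate GO term id: %s",
                               paste(unique(id[duplicated(id)]), collapse = ", "))
  ok_ns <- c("molecular_function", "biological_process", "cellular_component")
  if (!all(namespace %in% ok_ns))
    abort("unknown GO namespace: %s",
          paste(setdiff(unique(namespace), ok_ns), collapse = ", "))
  parents <- lapply(parents, as.character)
  names(parents) <- id
  dangling <- setdiff(unlist(parents, use.names = FALSE), id)
  if (length(dangling))
    abort("is_a parent(s) not defined in the graph: %s",
          paste(sort(unique(dangling)), collapse = ", "))
  g <- structure(
    list(terms = data.frame(id = id, name = name, namespace = namespace,
                            stringsAsFactors = FALSE),
         parents = parents,
         children = invert_edges(parents, id)),
    class = "go_graph")
  cyc <- find_cycle(parents, id)
  if (length(cyc)) abort("GO graph contains a cycle through: %s",
                         paste(cyc, collapse = " -> "))
  g
}

invert_edges <- function(parents, ids) {
  children <- setNames(vector("list", length(ids)), ids)
  for (child in names(parents))
    for (p in parents[[child]])
      children[[p]] <- c(children[[p]], child)
  children
}

# Returns a vector of ids forming a cycle, or character() if acyclic.
find_cycle <- function(parents, ids) {
  color <- setNames(integer(length(ids)), ids) # 0 white, 1 grey, 2 black
  for (start in ids) {
    if (color[[start]] != 0L) next
    stack <- list(list(id = start, next_parent = 1L))
    color[[start]] <- 1L
    path <- start
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ps <- parents[[top$id]]
      if (top$next_parent > length(ps)) {
        color[[top$id]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
      } else {
        stack[[length(stack)]]$next_parent <- top$next_parent + 1L
        p <- ps[[top$next_parent]]
        if (color[[p]] == 1L) return(c(path[which(path == p)[1]:length(path)], p))
        if (color[[p]] == 0L) {
          color[[p]] <- 1L
          stack[[length(stack) + 1L]] <- list(id = p, next_parent = 1L)
          path <- c(path, p)
        }
      }
    }
  }
  character()
}

#' @export
print.go_graph <- function(x, ...) {
  cat(sprintf("go_graph: %d terms (%s)\n", nrow(x$terms),
              paste(sprintf("%s=%d", names(table(x$terms$namespace)),
                            table(x$terms$namespace)), collapse = ", ")))
  invisible(x)
}

go_has_term <- function(go, id) id %in% go$terms$id

go_namespace <- function(go, id) {
  i <- match(id, go$terms$id)
  if (anyNA(i)) abort("unknown GO term: %s", paste(id[is.na(i)], collapse = ", "))
  go$terms$namespace[i]
}

#' Ancestors / descendants of a GO term along is_a edges
#'
#' @param go A [go_graph()].
#' @param id A single term id present in the graph.
#' @return Character vector of term ids, excluding `id` itself.
#' @export
go_ancestors <- function(go, id) {
  if (!go_has_term(go, id)) abort("unknown GO term: %s", id)
  seen <- character()
  frontier <- go$parents[[id]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(go$parents[new], use.names = FALSE))
  }
  sort(seen)
}

#' @rdname go_ancestors
#' @export
go_descendants <- function(go, id) {
  if (!go_has_term(go, id)) abort("unknown GO term: %s", id)
  seen <- character()
  frontier <- go$children[[id]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(go$children[new], use.names = FALSE))
  }
  sort(seen)
}

# TRUE iff `id` equals `anchor` or is a descendant of it.
go_is_a <- function(go, id, anchor) {
  id == anchor || anchor %in% go_ancestors(go, id)
}

#' Read a minimal OBO 1.2 flat file into a GO graph
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `namespace` and `is_a`
#' tags; everything else (including non-Term stanzas) is ignored.  The
#' resulting graph is checked for dangling `is_a` targets and cycles.
#'
#' @param path Path to an OBO flat file.
#' @return A [go_graph()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) == 3L) {
        val <- kv[3]
        switch(kv[2],
               id = { cur$id <- val },
               name = { cur$name <- val },
               namespace = { cur$namespace <- val },
               is_a = { cur$parents <- c(cur$parents, sub("\\s*!.*$", "", val)) })
      }
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) {
    warnf("OBO file '%s' contains no [Term] stanzas", path)
    return(go_graph(character(), character(), character(), list()))
  }
  go_graph(id = vapply(terms, `[[`, "", "id"),
           name = vapply(terms, function(t) t$name %||% t$id, ""),
           namespace = vapply(terms, function(t) t$namespace %||% "molecular_function", ""),
           parents = lapply(terms, `[[`, "parents"))
}

# Write a go_graph as a minimal OBO flat file (deterministic ordering).
write_obo <- function(go, path) {
  ord <- order(go$terms$id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in ord) {
    id <- go$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", go$terms$name[i]),
                 paste0("namespace: ", go$terms$namespace[i]),
                 if (length(go$parents[[id]]))
                   paste0("is_a: ", sort(go$parents[[id]])),
                 ""), con)
  }
  invisible(path)
}

#' GO anchor terms used for protease classification
#'
#' The protease definition is anchored at peptidase activity
#' (`GO:0008233`); the sub-classes are anchored at endopeptidase,
#' exopeptidase, aminopeptidase and carboxypeptidase activity.  These ids
#' are configuration shipped with the package's fixture graph and can be
#' overridden for graphs using a different subset.
#'
#' @return Named character vector with elements `protease`,
#'   `endopeptidase`, `exopeptidase`, `aminopeptidase`, `carboxypeptidase`.
#' @export
protease_anchor_terms <- function() {
  c(protease = "GO:0008233",
    endopeptidase = "GO:0004175",
    exopeptidase = "GO:0008238",
    aminopeptidase = "GO:0004177",
    carboxypeptidase = "GO:0004180")
}
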