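#' Construct a GO DAG object
#'
#' Builds the directed acyclic graph of GO terms used by the Wang-style
#' semantic similarity measures. Edges point child -> parent and are typed
#' (`is_a` or `part_of`); each type has a semantic contribution factor
#' strictly between 0 and 1 that attenuates S-values along the edge.
#'
#' @param terms Character vector of term identifiers.
#' @param parents Named list: for each term, a character vector of its parent
#'   terms (may be empty for roots). Names must cover `terms`.
#' @param types Named list parallel to `parents` giving the edge type of each
#'   child -> parent link (`"is_a"` or `"part_of"`). Defaults to all `is_a`.
#' @param aspect Named character vector giving each term's namespace
#'   (`"BP"`, `"MF"` or `"CC"`). Defaults to `"BP"` for every term.
#' @param contribution Named numeric vector of per-edge-type semantic
#'   contribution factors, each in (0, 1).
#' @return An object of class `go_dag`.
#' @seealso [read_go_obo()], [s_values()], [sim_go_terms()]
#' @export
go_dag <- function(terms, parents,
                   types = NULL,
                   aspect = NULL,
                   contribution = c(is_a = 0.8, part_of = 0.6)) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate term identifiers")
  if (!all(terms %in% names(parents))) {
    missing <- setdiff(terms, names(parents))
    stop("parents entry missing for term(s): ", paste(missing, collapse = ", "))
  }
  parents <- lapply(parents[terms], as.character)
  if (is.null(types)) {
    types <- lapply(parents, function(p) rep("is_a", length(p)))
  } else {
    types <- lapply(types[terms], as.character)
  }
  for (tm in terms) {
    p <- parents[[tm]]
    if (length(p) != length(types[[tm]])) {
      stop("parents/types length mismatch for term ", tm)
    }
    unknown <- setdiff(p, terms)
    if (length(unknown) > 0) {
      stop("term ", tm, " has parent(s) outside the DAG: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (is.null(aspect)) {
    aspect <- stats::setNames(rep("BP", length(terms)), terms)
  } else {
    aspect <- aspect[terms]
    if (anyNA(aspect)) stop("aspect missing for some terms")
  }
  bad_type <- setdiff(unique(unlist(types)), names(contribution))
  if (length(bad_type) > 0) {
    stop("edge type(s) without a contribution factor: ",
         paste(bad_type, collapse = ", "))
  }
  if (any(contribution <= 0 | contribution >= 1)) {
    stop("contribution factors must be strictly between 0 and 1")
  }
  dag <- structure(
    list(terms = terms, parents = parents, types = types,
         aspect = aspect, contribution = contribution,
         cache = new.env(parent = emptyenv())),
    class = "go_dag"
  )
  assert_acyclic(dag)
  dag
}

# Kahn's algorithm over child -> parent edges; errors on a cycle.
assert_acyclic <- function(dag) {
  n <- length(dag$terms)
  idx <- stats::setNames(seq_len(n), dag$terms)
  out_deg <- lengths(dag$parents)           # edges child -> parent
  children <- vector("list", n)             # reverse adjacency
  for (i in seq_len(n)) {
    for (p in dag$parents[[i]]) {
      j <- idx[[p]]
      children[[j]] <- c(children[[j]], i)
    }
  }
  queue <- which(out_deg == 0)
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      out_deg[[ch]] <- out_deg[[ch]] - 1L
      if (out_deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < n) stop("ontology graph contains a cycle")
  invisible(TRUE)
}

#' @export
print.go_dag <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat("GO DAG:", length(x$terms), "terms,", n_edges, "typed edges\n")
  cat("  aspects:", paste(names(table(x$aspect)), table(x$aspect),
                          sep = "=", collapse = ", "), "\n")
  cat("  contribution factors:",
      paste(names(x$contribution), x$contribution, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a GO ontology from an OBO 1.2 file
#'
#' Minimal OBO parser covering what the similarity computation needs:
#' `[Term]` stanzas with `id:`, `namespace:`, `is_a:` and
#' `relationship: part_of` lines. Obsolete terms are dropped. Parent links
#' pointing at terms absent from the file are dropped with a message.
#'
#' @param path Path to an OBO file.
#' @param contribution Per-edge-type semantic contribution factors.
#' @return A [go_dag] object.
#' @export
read_go_obo <- function(path, contribution = c(is_a = 0.8, part_of = 0.6)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  terms <- character(); parents <- list(); types <- list(); aspect <- character()
  cur <- NULL; cur_parents <- character(); cur_types <- character()
  cur_ns <- "BP"; cur_obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !cur_obsolete) {
      terms <<- c(terms, cur)
      parents[[cur]] <<- cur_parents
      types[[cur]] <<- cur_types
      aspect[[cur]] <<- cur_ns
    }
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", ln)          # trailing comments
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      cur <- NULL; cur_parents <- character(); cur_types <- character()
      cur_ns <- "BP"; cur_obsolete <- FALSE
      next
    }
    if (!in_term) next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (grepl("^namespace:", ln)) {
      ns <- trimws(sub("^namespace:", "", ln))
      cur_ns <- if (ns %in% names(ns_map)) ns_map[[ns]] else ns
    } else if (grepl("^is_a:", ln)) {
      cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", ln)))
      cur_types <- c(cur_types, "is_a")
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      cur_parents <- c(cur_parents,
                       trimws(sub("^relationship:\\s*part_of", "", ln)))
      cur_types <- c(cur_types, "part_of")
    } else if (grepl("^is_obsolete:\\s*true", ln)) {
      cur_obsolete <- TRUE
    }
  }
  flush()
  if (length(terms) == 0) stop("no terms found in OBO file: ", path)
  # drop dangling parent links (e.g. parents that are obsolete or external)
  dropped <- 0L
  for (tm in terms) {
    keep <- parents[[tm]] %in% terms
    dropped <- dropped + sum(!keep)
    parents[[tm]] <- parents[[tm]][keep]
    types[[tm]] <- types[[tm]][keep]
  }
  if (dropped > 0) {
    message("read_go_obo: dropped ", dropped,
            " parent link(s) to terms absent from the file")
  }
  go_dag(terms, parents, types, aspect, contribution)
}
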