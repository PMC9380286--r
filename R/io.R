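#' Read a PPI edge list
#'
#' Tab/whitespace-separated file with two protein identifiers per line
#' (extra columns ignored); `#` lines are comments. Self-interactions are
#' dropped, pairs are normalized so the lexicographically smaller identifier
#' comes first, and duplicates are removed.
#'
#' @param path Path to the edge-list file.
#' @return A `data.frame` with character columns `u`, `v` (u < v).
#' @export
read_ppi_edgelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no interaction records in ", path)
  fields <- strsplit(trimws(lines[idx]), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    bad <- idx[which(nf < 2)[1]]
    stop("malformed edge record at line ", bad, " of ", path,
         ": expected at least 2 fields")
  }
  u <- vapply(fields, `[[`, character(1), 1)
  v <- vapply(fields, `[[`, character(1), 2)
  keep_edge <- u != v
  u2 <- pmin(u[keep_edge], v[keep_edge])
  v2 <- pmax(u[keep_edge], v[keep_edge])
  dup <- duplicated(paste(u2, v2, sep = "\r"))
  out <- data.frame(u = u2[!dup], v = v2[!dup], stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("edge list is empty after removing self-loops")
  out
}

#' Read a gene expression matrix
#'
#' TSV or CSV: first column protein identifier, remaining columns numeric
#' expression levels at `m >= 2` sampling points. A header row is
#' auto-detected (non-numeric entries beyond the first column) and reported.
#'
#' @param path Path to the expression file.
#' @return Numeric matrix, one row per protein (rownames = protein IDs).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  cells <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- length(cells) > 1 &&
    anyNA(suppressWarnings(as.numeric(cells[-1])))
  message("read_expression: header row ",
          if (has_header) "detected" else "not detected", " in ", basename(path))
  dt <- data.table::fread(path, header = has_header, sep = sep,
                          data.table = FALSE)
  if (ncol(dt) < 3) stop("expression matrix needs >= 2 sampling points")
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) stop("duplicate protein identifiers in ", path)
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values in ", path)
  rownames(mat) <- ids
  colnames(mat) <- NULL
  mat
}

#' Read protein -> GO annotations from a GAF 2.x file
#'
#' Only the DB-object-ID (column 2) and GO-ID (column 5) are used.
#' Evidence codes (column 7) are not filtered by default; pass e.g.
#' `exclude_evidence = "IEA"` to drop electronically inferred annotations.
#'
#' @param path Path to a GAF file (`!` comment lines ignored).
#' @param exclude_evidence Character vector of evidence codes to drop.
#' @return Named list protein -> character vector of GO term IDs, class
#'   `go_annotation`.
#' @export
read_gaf <- function(path, exclude_evidence = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("no annotation records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 7)) {
    stop("malformed GAF record (fewer than 7 columns) in ", path)
  }
  prot <- vapply(fields, `[[`, character(1), 2)
  term <- vapply(fields, `[[`, character(1), 5)
  evid <- vapply(fields, `[[`, character(1), 7)
  keep <- !(evid %in% exclude_evidence)
  if (any(!keep)) {
    message("read_gaf: excluded ", sum(!keep), " annotation(s) by evidence code")
  }
  annotation_list(prot[keep], term[keep])
}

#' Read protein -> GO annotations from a simplified two-column TSV
#'
#' Each line: `protein<TAB>GO-ID`; `#` lines are comments.
#'
#' @param path Path to the TSV file.
#' @return Named list protein -> character vector of GO term IDs, class
#'   `go_annotation`.
#' @export
read_annotations_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("no annotation records in ", path)
  fields <- strsplit(lines, "[\t ]+")
  if (any(lengths(fields) < 2)) {
    stop("malformed annotation record (fewer than 2 fields) in ", path)
  }
  annotation_list(vapply(fields, `[[`, character(1), 1),
                  vapply(fields, `[[`, character(1), 2))
}

annotation_list <- function(proteins, terms) {
  ann <- lapply(split(terms, proteins), function(x) sort(unique(x)))
  structure(ann[order(names(ann))], class = "go_annotation")
}

#' Drop annotation terms absent from a GO DAG
#'
#' Terms not present in the ontology (obsolete or from another release) are
#' removed with a warning; proteins may end up unannotated but are kept.
#'
#' @param annotations A `go_annotation` list.
#' @param dag A [go_dag] object.
#' @return The pruned `go_annotation` list.
#' @export
prune_annotations <- function(annotations, dag) {
  stopifnot(inherits(dag, "go_dag"))
  dropped <- 0L
  out <- lapply(annotations, function(ts) {
    keep <- ts %in% dag$terms
    dropped <<- dropped + sum(!keep)
    ts[keep]
  })
  if (dropped > 0) {
    warning("prune_annotations: dropped ", dropped,
            " annotation(s) to terms absent from the ontology")
  }
  structure(out, class = "go_annotation")
}

#' Read an orthology table
#'
#' TSV with columns `protein<TAB>n_u`, where `n_u` counts the reference
#' species in which the protein has an ortholog. The total number of
#' reference species `N` is read from a header comment of the form
#' `# N=100` unless supplied via the `N` argument (which takes precedence).
#'
#' @param path Path to the orthology TSV.
#' @param N Optional total number of reference species, overriding the file.
#' @return List with `n` (named integer vector) and `N` (integer), class
#'   `orthology`.
#' @export
read_orthology <- function(path, N = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  if (is.null(N)) {
    nm <- regmatches(header, regexpr("N\\s*=\\s*[0-9]+", header))
    if (length(nm) == 0) {
      stop("total species count N not found in ", path,
           " (expected a '# N=<int>' header) and not supplied")
    }
    N <- as.integer(sub("N\\s*=\\s*", "", nm[[1]]))
  }
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0) stop("no orthology records in ", path)
  fields <- strsplit(body, "[\t ]+")
  if (any(lengths(fields) < 2)) stop("malformed orthology record in ", path)
  prot <- vapply(fields, `[[`, character(1), 1)
  n_u <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  if (anyNA(n_u)) stop("non-integer ortholog count in ", path)
  if (anyDuplicated(prot)) stop("duplicate protein in orthology table")
  orthology(stats::setNames(n_u, prot), N)
}

#' Construct an orthology table object
#'
#' @param n Named integer vector: protein -> number of reference species
#'   with an ortholog.
#' @param N Total number of reference species (positive integer).
#' @return An object of class `orthology`.
#' @export
orthology <- function(n, N) {
  N <- as.integer(N)
  if (is.na(N) || N <= 0) stop("N must be a positive integer")
  n <- stats::setNames(as.integer(n), names(n))
  if (is.null(names(n))) stop("n must be a named vector (protein -> count)")
  if (any(n < 0 | n > N)) stop("ortholog counts must satisfy 0 <= n_u <= N")
  structure(list(n = n, N = N), class = "orthology")
}

#' @export
print.orthology <- function(x, ...) {
  cat("Orthology table:", length(x$n), "proteins,", x$N,
      "reference species\n")
  invisible(x)
}

#' Read a gold-standard essential protein list
#'
#' One protein identifier per line; `#` lines are comments.
#'
#' @param path Path to the list file.
#' @return Character vector of unique protein IDs.
#' @export
read_gold_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- unique(lines[!grepl("^\\s*(#|$)", lines)])
  if (length(ids) == 0) stop("gold essential list is empty: ", path)
  ids
}

#' Write / read a weighted edge list
#'
#' TSV `u<TAB>v<TAB>weight` with 6-decimal fixed formatting and
#' deterministic (lexicographic) row order, for reproducible diffs.
#'
#' @param pin A [weighted_pin] object.
#' @param path Output / input path.
#' @return `write_weighted_pin()` returns `path` invisibly;
#'   `read_weighted_pin()` returns a [weighted_pin].
#' @export
write_weighted_pin <- function(pin, path) {
  stopifnot(inherits(pin, "weighted_pin"))
  e <- pin$edges[order(pin$edges$u, pin$edges$v), , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%.6f", e$u, e$v, e$weight), path)
  invisible(path)
}

#' @rdname write_weighted_pin
#' @export
read_weighted_pin <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("u", "v", "weight"),
                          colClasses = list(character = 1:2, numeric = 3),
                          data.table = FALSE)
  weighted_pin(dt)
}

#' Write a ranking table
#'
#' TSV `rank<TAB>protein<TAB>score<TAB>method` in selection order.
#'
#' @param ranking A `ranked_candidates` data frame from [select_seeds()] or
#'   a baseline.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranked_candidates"))
  method <- attr(ranking, "method")
  lines <- c("rank\tprotein\tscore\tmethod",
             sprintf("%d\t%s\t%.10g\t%s", ranking$rank, ranking$protein,
                     ranking$score, method))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranking table written by [write_ranking()]
#'
#' @param path Input path.
#' @return A `ranked_candidates` data frame.
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ranked_candidates(df$protein, df$score,
                    method = if (nrow(df) > 0) df$method[[1]] else "unknown")
}
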