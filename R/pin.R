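#' Construct a weighted protein interaction network
#'
#' The container used throughout the package: an undirected simple graph
#' with symmetric non-negative edge weights and an adjacency index for O(1)
#' neighbor lookup.
#'
#' @param edges A `data.frame` with columns `u`, `v` (character) and
#'   `weight` (numeric, >= 0). Self-loops are rejected; duplicate
#'   (unordered) pairs are rejected.
#' @param nodes Optional character vector of node identifiers; defaults to
#'   the identifiers appearing in `edges`. Extra isolated nodes are allowed.
#' @return An object of class `weighted_pin` with elements `nodes`
#'   (sorted character vector), `edges` (normalized data frame, `u < v`) and
#'   `adj` (per-node integer neighbor indices and weights).
#' @export
weighted_pin <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("u", "v", "weight") %in% names(edges)))
  if (nrow(edges) == 0) stop("edge list is empty")
  u <- as.character(edges$u)
  v <- as.character(edges$v)
  w <- as.numeric(edges$weight)
  if (any(u == v)) stop("self-loops are not allowed")
  if (anyNA(w) || any(w < 0)) stop("edge weights must be non-negative numbers")
  uu <- pmin(u, v)
  vv <- pmax(u, v)
  if (anyDuplicated(paste0(uu, "\r", vv))) stop("duplicate edges")
  nodes <- sort(unique(c(uu, vv, as.character(nodes))))
  idx <- stats::setNames(seq_along(nodes), nodes)
  ui <- idx[uu]
  vi <- idx[vv]
  adj <- rep(list(list(idx = integer(0), w = numeric(0))), length(nodes))
  ord <- order(ui, vi)
  for (e in ord) {
    adj[[ui[[e]]]]$idx <- c(adj[[ui[[e]]]]$idx, vi[[e]])
    adj[[ui[[e]]]]$w   <- c(adj[[ui[[e]]]]$w, w[[e]])
    adj[[vi[[e]]]]$idx <- c(adj[[vi[[e]]]]$idx, ui[[e]])
    adj[[vi[[e]]]]$w   <- c(adj[[vi[[e]]]]$w, w[[e]])
  }
  structure(
    list(nodes = nodes,
         edges = data.frame(u = uu, v = vv, weight = w,
                            stringsAsFactors = FALSE),
         adj = adj),
    class = "weighted_pin"
  )
}

#' @export
print.weighted_pin <- function(x, ...) {
  cat("Weighted PIN:", length(x$nodes), "proteins,", nrow(x$edges),
      "interactions\n")
  cat("  weight range: [", format(min(x$edges$weight), digits = 4), ", ",
      format(max(x$edges$weight), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Weighted degree of every protein
#'
#' `Inf_topo(u) = sum over neighbors v of w(u, v)`: the total influence mass
#' a protein can push into the network in one step.
#'
#' @param pin A [weighted_pin].
#' @return Named numeric vector over all nodes (0 for isolated nodes).
#' @export
weighted_degree <- function(pin) {
  stopifnot(inherits(pin, "weighted_pin"))
  stats::setNames(vapply(pin$adj, function(a) sum(a$w), numeric(1)),
                  pin$nodes)
}

#' Unweighted degree of every protein
#'
#' @param pin A [weighted_pin].
#' @return Named integer vector over all nodes.
#' @export
node_degree <- function(pin) {
  stopifnot(inherits(pin, "weighted_pin"))
  stats::setNames(vapply(pin$adj, function(a) length(a$idx), integer(1)),
                  pin$nodes)
}

#' Weight of one PIN edge from expression and GO evidence
#'
#' `w(u, v) = Sim_GO(u, v) * PCC+(u, v)`, where `PCC+` applies the
#' negative-correlation policy (default: clamp negatives to 0). A protein
#' missing from the expression matrix contributes a PCC factor of 0; an
#' unannotated protein contributes a GO factor of 0. Either way the edge is
#' kept (with weight 0) so orthology can still rank the node.
#'
#' @param u,v Protein identifiers.
#' @param expression Numeric matrix (rows = proteins) or `NULL` to skip the
#'   co-expression factor (treated as 1).
#' @param annotations A `go_annotation` list or `NULL` to skip the GO factor
#'   (treated as 1).
#' @param dag A [go_dag], required when `annotations` is given.
#' @param pcc_policy One of `"clamp"`, `"absolute"`, `"raw"`.
#' @return A single numeric weight.
#' @export
edge_weight <- function(u, v, expression = NULL, annotations = NULL,
                        dag = NULL, pcc_policy = "clamp") {
  pcc <- if (is.null(expression)) {
    1
  } else if (!(u %in% rownames(expression)) || !(v %in% rownames(expression))) {
    0
  } else {
    apply_pcc_policy(compute_pcc(expression[u, ], expression[v, ]), pcc_policy)
  }
  sim <- if (is.null(annotations)) {
    1
  } else {
    stopifnot(inherits(dag, "go_dag"))
    sim_go_proteins(annotations[[u]] %||% character(0),
                    annotations[[v]] %||% character(0), dag)
  }
  sim * pcc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the weighted PIN from raw inputs
#'
#' Combines the raw PPI topology with per-edge weights
#' `Sim_GO(u,v) * PCC+(u,v)`. All proteins appearing in the edge list are
#' retained even when they lack expression or annotation data (their
#' incident edges then carry weight 0).
#'
#' @param edges PPI pairs as returned by [read_ppi_edgelist()] (data frame
#'   with columns `u`, `v`).
#' @param expression Numeric expression matrix (rows = proteins) or `NULL`.
#' @param annotations A `go_annotation` list or `NULL`.
#' @param dag A [go_dag], required when `annotations` is given; annotation
#'   terms absent from it are pruned first (with a warning).
#' @param pcc_policy Negative-PCC policy: `"clamp"` (default), `"absolute"`
#'   or `"raw"` (with `"raw"`, negative products are floored at 0 to keep
#'   the container invariant).
#' @return A [weighted_pin].
#' @export
build_weighted_pin <- function(edges, expression = NULL, annotations = NULL,
                               dag = NULL, pcc_policy = "clamp") {
  if (nrow(edges) == 0) stop("edge list is empty")
  if (!is.null(annotations)) {
    stopifnot(inherits(dag, "go_dag"))
    annotations <- prune_annotations(annotations, dag)
  }
  w <- vapply(seq_len(nrow(edges)), function(i) {
    edge_weight(edges$u[[i]], edges$v[[i]], expression, annotations, dag,
                pcc_policy)
  }, numeric(1))
  n_neg <- sum(w < 0)
  if (n_neg > 0) {
    message("build_weighted_pin: floored ", n_neg,
            " negative edge weight(s) at 0 (pcc_policy = \"", pcc_policy, "\")")
    w <- pmax(w, 0)
  }
  weighted_pin(data.frame(u = edges$u, v = edges$v, weight = w,
                          stringsAsFactors = FALSE))
}
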