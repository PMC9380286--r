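#' S-values of a GO term and its ancestors
#'
#' Wang-style semantic contributions: the query term contributes 1 to
#' itself, and each ancestor `t` contributes
#' `S(t) = max over child edges of (contribution factor * S(child))`,
#' maximized over all paths from the query term up to `t`. The returned map
#' covers exactly the query term and its ancestor closure.
#'
#' @param term A term identifier present in `dag`.
#' @param dag A [go_dag] object.
#' @return Named numeric vector of S-values in (0, 1], including
#'   `term` itself with value 1.
#' @examples
#' dag <- go_dag(c("A", "B", "C"),
#'               parents = list(A = "B", B = "C", C = character()))
#' s_values("A", dag)  # A = 1, B = 0.8, C = 0.64
#' @export
s_values <- function(term, dag) {
  stopifnot(inherits(dag, "go_dag"))
  if (!term %in% dag$terms) stop("unknown GO term: ", term)
  key <- paste0("S:", term)
  cached <- get0(key, envir = dag$cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  # ancestor closure via BFS, then one relaxation pass in topological order
  # (children before parents) so each max is final when read
  closure <- term
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, closure)
    closure <- c(closure, nxt)
    frontier <- nxt
  }
  order <- topo_order_closure(closure, dag)
  s <- stats::setNames(rep(-Inf, length(closure)), closure)
  s[[term]] <- 1
  for (tm in order) {
    if (s[[tm]] == -Inf) next   # unreachable within closure (cannot happen)
    ps <- dag$parents[[tm]]
    ty <- dag$types[[tm]]
    for (i in seq_along(ps)) {
      cand <- dag$contribution[[ty[[i]]]] * s[[tm]]
      if (cand > s[[ps[[i]]]]) s[[ps[[i]]]] <- cand
    }
  }
  assign(key, s, envir = dag$cache)
  s
}

# topological order of a closure (children before parents), restricted to
# edges inside the closure
topo_order_closure <- function(closure, dag) {
  idx <- stats::setNames(seq_along(closure), closure)
  out_deg <- integer(length(closure))   # number of unprocessed children
  parents_in <- lapply(closure, function(tm) {
    p <- dag$parents[[tm]]
    p[p %in% closure]
  })
  for (i in seq_along(closure)) {
    for (p in parents_in[[i]]) out_deg[[idx[[p]]]] <- out_deg[[idx[[p]]]] + 1L
  }
  queue <- which(out_deg == 0L)          # terms with no children in closure
  # out_deg here counts in-closure children still pending; seed with terms
  # that have none (the query term's "leaf end")
  order <- integer(0)
  pending <- out_deg
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    order <- c(order, v)
    for (p in parents_in[[v]]) {
      j <- idx[[p]]
      pending[[j]] <- pending[[j]] - 1L
      if (pending[[j]] == 0L) queue <- c(queue, j)
    }
  }
  closure[order]
}

#' Semantic similarity of two GO terms
#'
#' Wang-style similarity: with `T1`, `T2` the ancestor closures (term plus
#' ancestors) and `S1`, `S2` the corresponding S-value maps,
#' \deqn{Sim(t_1, t_2) = \frac{\sum_{t \in T_1 \cap T_2} (S_1(t) + S_2(t))}
#'   {\sum_{t \in T_1} S_1(t) + \sum_{t \in T_2} S_2(t)}.}
#' Terms in different ontology aspects (namespaces) are not comparable and
#' score 0.
#'
#' @param t1,t2 Term identifiers present in `dag`.
#' @param dag A [go_dag] object.
#' @return A number in `[0, 1]`; 1 iff the terms have identical S-value maps.
#' @export
sim_go_terms <- function(t1, t2, dag) {
  stopifnot(inherits(dag, "go_dag"))
  if (!t1 %in% dag$terms) stop("unknown GO term: ", t1)
  if (!t2 %in% dag$terms) stop("unknown GO term: ", t2)
  if (dag$aspect[[t1]] != dag$aspect[[t2]]) return(0)
  if (t1 == t2) return(1)
  key <- if (t1 < t2) paste0("P:", t1, "|", t2) else paste0("P:", t2, "|", t1)
  cached <- get0(key, envir = dag$cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  s1 <- s_values(t1, dag)
  s2 <- s_values(t2, dag)
  common <- intersect(names(s1), names(s2))
  val <- if (length(common) == 0) 0 else
    sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
  assign(key, val, envir = dag$cache)
  val
}

#' Semantic similarity between a GO term and an annotated protein
#'
#' The best match of `t` against the protein's annotation set:
#' `max_i Sim(t, t_P^i)`.
#'
#' @param t A term identifier.
#' @param terms_p Non-empty character vector of the protein's GO terms.
#' @param dag A [go_dag] object.
#' @return A number in `[0, 1]`.
#' @export
sim_go_term_protein <- function(t, terms_p, dag) {
  if (length(terms_p) == 0) {
    stop("protein has an empty annotation set; apply the unannotated-protein",
         " policy before calling sim_go_term_protein()")
  }
  max(vapply(terms_p, function(tp) sim_go_terms(t, tp, dag), numeric(1)))
}

#' Semantic similarity of two proteins
#'
#' Best-match average over both annotation sets: with `u` annotated by `m`
#' terms and `v` by `n` terms,
#' \deqn{Sim_{GO}(u,v) = \frac{\sum_i Sim(t_u^i, v) + \sum_j Sim(t_v^j, u)}
#'   {m + n}.}
#' If either protein is unannotated there is no semantic evidence and the
#' similarity is 0.
#'
#' @param terms_u,terms_v Character vectors of GO terms annotating the two
#'   proteins (possibly empty).
#' @param dag A [go_dag] object.
#' @return A number in `[0, 1]`.
#' @export
sim_go_proteins <- function(terms_u, terms_v, dag) {
  m <- length(terms_u)
  n <- length(terms_v)
  if (m == 0 || n == 0) return(0)
  su <- vapply(terms_u, function(t) sim_go_term_protein(t, terms_v, dag),
               numeric(1))
  sv <- vapply(terms_v, function(t) sim_go_term_protein(t, terms_u, dag),
               numeric(1))
  (sum(su) + sum(sv)) / (m + n)
}
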