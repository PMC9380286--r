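# Independent oracles and random-instance generators. Everything here is
# deliberately naive (brute force, full rescans) so it cannot share a bug
# with the package's optimized paths.

# --- S-values by exhaustive path enumeration -------------------------------

# all upward paths term -> ancestor, maximizing the product of edge factors
oracle_s_values <- function(term, dag) {
  s <- stats::setNames(1, term)
  walk <- function(node, prod) {
    ps <- dag$parents[[node]]
    ty <- dag$types[[node]]
    for (i in seq_along(ps)) {
      val <- prod * dag$contribution[[ty[[i]]]]
      p <- ps[[i]]
      if (is.na(s[p]) || val > s[[p]]) s[p] <<- val
      walk(p, val)
    }
  }
  walk(term, 1)
  s
}

oracle_sim_terms <- function(t1, t2, dag) {
  if (dag$aspect[[t1]] != dag$aspect[[t2]]) return(0)
  s1 <- oracle_s_values(t1, dag)
  s2 <- oracle_s_values(t2, dag)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

oracle_sim_proteins <- function(terms_u, terms_v, dag) {
  if (length(terms_u) == 0 || length(terms_v) == 0) return(0)
  best <- function(t, ts) max(sapply(ts, function(x) oracle_sim_terms(t, x, dag)))
  (sum(sapply(terms_u, best, ts = terms_v)) +
     sum(sapply(terms_v, best, ts = terms_u))) /
    (length(terms_u) + length(terms_v))
}

# random DAG: term i > 1 gets 1-2 parents among earlier terms
random_dag <- function(n_terms, n_aspects = 1,
                       contribution = c(is_a = 0.8, part_of = 0.6)) {
  terms <- sprintf("T%02d", seq_len(n_terms))
  roots <- seq_len(n_aspects)
  parents <- list(); types <- list(); aspect <- character(0)
  asp_labels <- c("BP", "MF", "CC")[seq_len(n_aspects)]
  asp <- stats::setNames(asp_labels[1 + (seq_len(n_terms) - 1) %% n_aspects],
                         terms)
  for (i in seq_len(n_terms)) {
    if (i <= n_aspects) {
      parents[[terms[[i]]]] <- character(0)
      types[[terms[[i]]]] <- character(0)
      next
    }
    pool <- which(asp[seq_len(i - 1)] == asp[[i]])
    np <- min(length(pool), sample(1:2, 1))
    ps <- terms[sample(pool, np)]
    parents[[terms[[i]]]] <- ps
    types[[terms[[i]]]] <- sample(names(contribution), np, replace = TRUE)
  }
  go_dag(terms, parents, types, asp, contribution)
}

# --- weighted PIN / greedy-selection oracles -------------------------------

random_pin <- function(n, edge_prob = 0.3, max_w = 1) {
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < edge_prob
  if (!any(keep)) keep[sample(ncol(pairs), 1)] <- TRUE
  weighted_pin(data.frame(
    u = ids[pairs[1, keep]], v = ids[pairs[2, keep]],
    weight = stats::runif(sum(keep), 0, max_w),
    stringsAsFactors = FALSE
  ), nodes = ids)
}

random_orthology <- function(ids, N = 100) {
  orthology(stats::setNames(sample.int(N + 1, length(ids), replace = TRUE) - 1L,
                            ids), N)
}

# naive greedy: full rescan each iteration, influence scores recomputed from
# scratch from the accumulated (t, tt); mirrors the published update rule but
# shares no selection machinery with select_seeds()
oracle_select <- function(pin, orthology, k, lambda, p,
                          tie_break = "lexicographic") {
  ids <- pin$nodes
  n <- length(ids)
  wdeg <- unname(imepp::weighted_degree(pin))
  max_inf <- max(wdeg)
  n_u <- orthology$n[ids]; n_u[is.na(n_u)] <- 0L
  os <- n_u / orthology$N
  is_os <- if (max(os) > 0) os / max(os) else rep(0, n)
  t_cnt <- integer(n); tt <- numeric(n); seed <- logical(n)
  rk <- if (tie_break == "lexicographic") order(order(ids)) else seq_len(n)
  out <- character(0)
  for (iter in seq_len(k)) {
    is_topo <- numeric(n)
    for (v in seq_len(n)) {
      if (t_cnt[[v]] == 0L) {        # undiscounted: plain normalized degree
        is_topo[[v]] <- wdeg[[v]] / max_inf
        next
      }
      id_v <- (wdeg[[v]] - tt[[v]] -
                 (wdeg[[v]] - tt[[v]]) * t_cnt[[v]] * p) * p
      if (id_v < 0) id_v <- 0
      is_topo[[v]] <- (id_v / p) / max_inf
    }
    is_val <- lambda * is_os + (1 - lambda) * is_topo
    cand <- which(!seed)
    best <- cand[order(-is_val[cand], rk[cand])][1]
    out <- c(out, ids[[best]])
    seed[[best]] <- TRUE
    a <- pin$adj[[best]]
    for (j in seq_along(a$idx)) {
      v <- a$idx[[j]]
      if (!seed[[v]]) {
        t_cnt[[v]] <- t_cnt[[v]] + 1L
        tt[[v]] <- tt[[v]] + a$w[[j]]
      }
    }
  }
  out
}

exact_discount <- function(inf, tt, t, p) (1 - p)^t * (inf - tt) * p
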