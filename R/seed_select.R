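# Indexed binary max-heap over item indices 1..n with mutable keys.
# Ties are broken by a fixed per-item rank (smaller rank wins), so extraction
# order is fully deterministic. Backed by an environment; extract-max and
# key updates are O(log n).
ipq_new <- function(keys, tie_rank) {
  n <- length(keys)
  e <- new.env(parent = emptyenv())
  e$key <- keys
  e$rank <- tie_rank
  e$heap <- seq_len(n)       # heap slot -> item
  e$pos <- seq_len(n)        # item -> heap slot (0 once removed)
  e$size <- n
  higher <- function(a, b) {
    e$key[[a]] > e$key[[b]] ||
      (e$key[[a]] == e$key[[b]] && e$rank[[a]] < e$rank[[b]])
  }
  swap <- function(i, j) {
    a <- e$heap[[i]]; b <- e$heap[[j]]
    e$heap[[i]] <- b; e$heap[[j]] <- a
    e$pos[[a]] <- j; e$pos[[b]] <- i
  }
  sift_up <- function(i) {
    while (i > 1) {
      par <- i %/% 2L
      if (higher(e$heap[[i]], e$heap[[par]])) { swap(i, par); i <- par }
      else break
    }
  }
  sift_down <- function(i) {
    repeat {
      l <- 2L * i; r <- l + 1L; best <- i
      if (l <= e$size && higher(e$heap[[l]], e$heap[[best]])) best <- l
      if (r <= e$size && higher(e$heap[[r]], e$heap[[best]])) best <- r
      if (best == i) break
      swap(i, best); i <- best
    }
  }
  e$build <- function() {
    for (i in rev(seq_len(e$size %/% 2L))) sift_down(i)
  }
  e$extract_max <- function() {
    if (e$size == 0) stop("priority queue is empty")
    top <- e$heap[[1]]
    swap(1L, e$size)
    e$pos[[top]] <- 0L
    e$size <- e$size - 1L
    if (e$size > 0) sift_down(1L)
    top
  }
  e$set_key <- function(item, key) {
    slot <- e$pos[[item]]
    if (slot == 0L) return(invisible(NULL))   # already extracted
    old <- e$key[[item]]
    e$key[[item]] <- key
    if (key > old) sift_up(slot) else if (key < old) sift_down(slot)
    invisible(NULL)
  }
  e$build()
  e
}

tie_ranks <- function(ids, tie_break) {
  if (tie_break == "lexicographic") order(order(ids)) else seq_along(ids)
}

ranked_candidates <- function(protein, score, method, params = NULL) {
  structure(
    data.frame(rank = seq_along(protein), protein = protein, score = score,
               stringsAsFactors = FALSE),
    method = method, params = params,
    class = c("ranked_candidates", "data.frame")
  )
}

#' @export
print.ranked_candidates <- function(x, n = 10, ...) {
  cat("Ranked candidates (", attr(x, "method"), "): ", nrow(x),
      " proteins\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Greedy influence-discount selection of candidate essential proteins
#'
#' Iterates k times: extract the non-seed protein with the largest influence
#' score (ties broken by the configured policy), mark it as a seed, and
#' discount the scores of its non-seed neighbors via [update_after_seed()].
#' An indexed max-heap gives O(log |V|) per extraction/score update.
#'
#' @param pin A [weighted_pin].
#' @param state An `influence_state` from [init_influence()] (it is not
#'   modified; selection works on a copy).
#' @param k Number of candidates; values above the node count are truncated
#'   with a warning.
#' @return A `ranked_candidates` data frame (`rank`, `protein`, `score`)
#'   with the score each protein had at the moment of its selection;
#'   attribute `method = "imepp"`.
#' @export
select_seeds <- function(pin, state, k) {
  stopifnot(inherits(pin, "weighted_pin"), inherits(state, "influence_state"))
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  n <- length(state$ids)
  if (k > n) {
    warning("k = ", k, " exceeds the number of proteins (", n,
            "); truncating")
    k <- n
  }
  pq <- ipq_new(state$is, tie_ranks(state$ids, state$tie_break))
  sel_protein <- character(k)
  sel_score <- numeric(k)
  for (iter in seq_len(k)) {
    s <- pq$extract_max()
    sel_protein[[iter]] <- state$ids[[s]]
    sel_score[[iter]] <- state$is[[s]]
    state$seed[[s]] <- TRUE
    state <- update_after_seed(state$ids[[s]], pin, state)
    for (v in pin$adj[[s]]$idx) {
      if (!state$seed[[v]]) pq$set_key(v, state$is[[v]])
    }
  }
  ranked_candidates(sel_protein, sel_score, method = "imepp",
                    params = list(lambda = state$lambda, p = state$p, k = k,
                                  tie_break = state$tie_break))
}

#' Degree-discount baseline
#'
#' Classic influence-maximization heuristic on the unweighted view of the
#' PIN: maintain `dd(v) = d(v) - 2 t(v) - (d(v) - t(v)) t(v) p` where
#' `t(v)` counts seed neighbors; repeatedly pick the maximum `dd`, then
#' increment `t` for the new seed's neighbors.
#'
#' @param pin A [weighted_pin] (weights ignored).
#' @param k Number of candidates (truncated to the node count with a
#'   warning).
#' @param p Spread probability.
#' @param tie_break `"lexicographic"` or `"insertion"`.
#' @return A `ranked_candidates` data frame, method `"dd"`.
#' @export
degree_discount_baseline <- function(pin, k, p = 0.001,
                                     tie_break = "lexicographic") {
  stopifnot(inherits(pin, "weighted_pin"))
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  n <- length(pin$nodes)
  if (k > n) {
    warning("k = ", k, " exceeds the number of proteins (", n,
            "); truncating")
    k <- n
  }
  d <- as.numeric(unname(node_degree(pin)))
  t <- integer(n)
  seed <- logical(n)
  pq <- ipq_new(d, tie_ranks(pin$nodes, tie_break))
  sel_protein <- character(k)
  sel_score <- numeric(k)
  for (iter in seq_len(k)) {
    s <- pq$extract_max()
    sel_protein[[iter]] <- pin$nodes[[s]]
    sel_score[[iter]] <- d[[s]] - 2 * t[[s]] - (d[[s]] - t[[s]]) * t[[s]] * p
    seed[[s]] <- TRUE
    for (v in pin$adj[[s]]$idx) {
      if (seed[[v]]) next
      t[[v]] <- t[[v]] + 1L
      pq$set_key(v, d[[v]] - 2 * t[[v]] - (d[[v]] - t[[v]]) * t[[v]] * p)
    }
  }
  ranked_candidates(sel_protein, sel_score, method = "dd",
                    params = list(p = p, k = k, tie_break = tie_break))
}

#' Degree-centrality baseline
#'
#' Top-k proteins by unweighted degree with a stable, deterministic
#' tie-break.
#'
#' @param pin A [weighted_pin] (weights ignored).
#' @param k Number of candidates (truncated to the node count with a
#'   warning).
#' @param tie_break `"lexicographic"` or `"insertion"`.
#' @return A `ranked_candidates` data frame, method `"dc"`.
#' @export
degree_centrality_baseline <- function(pin, k, tie_break = "lexicographic") {
  stopifnot(inherits(pin, "weighted_pin"))
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  n <- length(pin$nodes)
  if (k > n) {
    warning("k = ", k, " exceeds the number of proteins (", n,
            "); truncating")
    k <- n
  }
  d <- unname(node_degree(pin))
  rk <- tie_ranks(pin$nodes, tie_break)
  ord <- order(-d, rk)[seq_len(k)]
  ranked_candidates(pin$nodes[ord], as.numeric(d[ord]), method = "dc",
                    params = list(k = k, tie_break = tie_break))
}

#' One-call ranking from a weighted PIN and an orthology table
#'
#' Convenience wrapper: [init_influence()] + [select_seeds()] for
#' `method = "imepp"`, or the corresponding baseline.
#'
#' @param pin A [weighted_pin].
#' @param orthology An [orthology] table (ignored by the baselines).
#' @param k Number of candidates.
#' @param method `"imepp"`, `"dd"` or `"dc"`.
#' @param params An [imepp_params] list (lambda, p, tie-break).
#' @return A `ranked_candidates` data frame.
#' @export
rank_proteins <- function(pin, orthology = NULL, k = 100,
                          method = c("imepp", "dd", "dc"),
                          params = imepp_params()) {
  method <- match.arg(method)
  switch(method,
    imepp = {
      if (is.null(orthology)) stop("method \"imepp\" requires an orthology table")
      select_seeds(pin, init_influence(pin, orthology, params), k)
    },
    dd = degree_discount_baseline(pin, k, p = params$p,
                                  tie_break = params$tie_break),
    dc = degree_centrality_baseline(pin, k, tie_break = params$tie_break)
  )
}
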