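#' Parameters for influence-based ranking
#'
#' @param lambda Trade-off in `[0, 1]` between orthology (`lambda = 1`) and
#'   network topology (`lambda = 0`). Default 0.2: topology carries most of
#'   the signal, orthology refines it.
#' @param p Spread probability of the independent cascade model, in (0, 1).
#'   Default 0.001, small enough that the first-order influence-discount
#'   approximation is essentially exact.
#' @param k Number of candidates to select.
#' @param tie_break `"lexicographic"` (default; smaller protein ID wins on
#'   equal scores, dataset-order independent) or `"insertion"` (node order
#'   of the PIN container).
#' @param pcc_policy Negative-PCC policy recorded for provenance.
#' @return A list of class `imepp_params`.
#' @export
imepp_params <- function(lambda = 0.2, p = 0.001, k = 100L,
                         tie_break = c("lexicographic", "insertion"),
                         pcc_policy = "clamp") {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0, lambda <= 1)
  stopifnot(is.numeric(p), length(p) == 1, p > 0, p < 1)
  k <- as.integer(k)
  stopifnot(!is.na(k), k >= 1)
  tie_break <- match.arg(tie_break)
  structure(list(lambda = lambda, p = p, k = k, tie_break = tie_break,
                 pcc_policy = pcc_policy),
            class = "imepp_params")
}

#' Initialize per-protein influence scores
#'
#' Computes, for every protein `u` in the PIN:
#' * `Inf_topo(u)`: weighted degree, the topological influence mass;
#' * `IS_topo(u) = Inf_topo(u) / max_v Inf_topo(v)`;
#' * `OS(u) = n_u / N` (ortholog fraction; 0 for proteins absent from the
#'   table) and `IS_OS(u) = OS(u) / max_v OS(v)`;
#' * `IS(u) = lambda * IS_OS(u) + (1 - lambda) * IS_topo(u)`.
#'
#' The normalizer `max Inf_topo` is fixed here and never updated by later
#' discounts. Seed-neighbor counters `t` and seed-edge weight sums `tt`
#' start at 0.
#'
#' @param pin A [weighted_pin].
#' @param orthology An [orthology] table.
#' @param params An [imepp_params] list.
#' @return An object of class `influence_state`.
#' @export
init_influence <- function(pin, orthology, params = imepp_params()) {
  stopifnot(inherits(pin, "weighted_pin"), inherits(orthology, "orthology"),
            inherits(params, "imepp_params"))
  ids <- pin$nodes
  inf_topo <- unname(weighted_degree(pin))
  max_inf <- max(inf_topo)
  if (max_inf == 0 && params$lambda < 1) {
    stop("all weighted degrees are zero: topology is uninformative ",
         "(set lambda = 1 to rank by orthology alone)")
  }
  n_u <- unname(orthology$n[ids])
  n_u[is.na(n_u)] <- 0L
  os <- n_u / orthology$N
  max_os <- max(os)
  if (max_os == 0 && params$lambda > 0) {
    stop("all orthologous scores are zero: orthology is uninformative ",
         "(set lambda = 0 to rank by topology alone)")
  }
  is_topo <- if (max_inf > 0) inf_topo / max_inf else rep(0, length(ids))
  is_os <- if (max_os > 0) os / max_os else rep(0, length(ids))
  is_val <- params$lambda * is_os + (1 - params$lambda) * is_topo
  structure(
    list(ids = ids,
         lambda = params$lambda, p = params$p,
         tie_break = params$tie_break,
         inf_topo = inf_topo, max_inf_topo = max_inf,
         is_topo = is_topo, is_os = is_os, is = is_val,
         t = integer(length(ids)), tt = numeric(length(ids)),
         seed = logical(length(ids))),
    class = "influence_state"
  )
}

#' @export
print.influence_state <- function(x, ...) {
  cat("Influence state:", length(x$ids), "proteins,", sum(x$seed),
      "seed(s); lambda =", x$lambda, ", p =", x$p, "\n")
  invisible(x)
}

state_index <- function(state, v) {
  i <- match(v, state$ids)
  if (is.na(i)) stop("unknown protein: ", v)
  i
}

#' Influence discount of a non-seed protein
#'
#' Expected residual one-step influence of `v` under the independent
#' cascade model with spread probability `p`, given that `t(v)` of its
#' neighbors are already seeds connected by total edge weight `tt(v)`:
#' \deqn{ID(v) = (Inf_{topo}(v) - tt(v) -
#'   (Inf_{topo}(v) - tt(v)) \cdot t(v) \cdot p) \cdot p,}
#' the first-order expansion of the exact form
#' \eqn{(1-p)^{t(v)} (Inf_{topo}(v) - tt(v))\, p}, valid when
#' `t(v) * p` is small. A negative value (possible only when
#' `t(v) * p >= 1`, outside the approximation's validity) is floored at 0.
#' With no seed neighbors the discount reduces to `Inf_topo(v) * p` exactly.
#'
#' @param v A protein identifier.
#' @param state An `influence_state`.
#' @return A non-negative number.
#' @export
influence_discount <- function(v, state) {
  stopifnot(inherits(state, "influence_state"))
  i <- state_index(state, v)
  if (state$seed[[i]]) stop("protein ", v, " is already a seed")
  id_discount(state$inf_topo[[i]], state$tt[[i]], state$t[[i]], state$p)
}

# scalar core shared by the public function and the seed-update loop;
# arithmetic order matters for bit-level reproducibility of ties
id_discount <- function(inf, tt, t, p) {
  val <- (inf - tt - (inf - tt) * t * p) * p
  if (val < 0) {
    # happens when t*p >= 1 (outside the approximation's validity) or when
    # rounding makes the accumulated tt exceed Inf_topo by an ulp
    message("influence discount floored at 0")
    val <- 0
  }
  val
}

#' Update influence scores after selecting a seed
#'
#' For every non-seed neighbor `v` of the newly selected seed: increment the
#' seed-neighbor count `t(v)`, add the connecting edge weight to `tt(v)`,
#' recompute the influence discount from the (unchanged) initial
#' `Inf_topo(v)` and the accumulated `(t, tt)`, and set
#' `IS_topo(v) = (ID(v)/p) / max Inf_topo` with `IS` recomposed from the
#' unchanged `IS_OS(v)`. Nodes not adjacent to the new seed are untouched.
#'
#' @param s_new Identifier of the protein just marked as seed (it must
#'   already have `seed = TRUE` in `state`; [select_seeds()] handles this).
#' @param pin The [weighted_pin] the state was initialized from.
#' @param state An `influence_state`.
#' @return The updated `influence_state`.
#' @export
update_after_seed <- function(s_new, pin, state) {
  stopifnot(inherits(pin, "weighted_pin"), inherits(state, "influence_state"))
  s <- state_index(state, s_new)
  if (!state$seed[[s]]) stop("protein ", s_new, " has not been marked as seed")
  a <- pin$adj[[s]]
  for (j in seq_along(a$idx)) {
    v <- a$idx[[j]]
    if (state$seed[[v]]) next
    state$t[[v]] <- state$t[[v]] + 1L
    state$tt[[v]] <- state$tt[[v]] + a$w[[j]]
    id_v <- id_discount(state$inf_topo[[v]], state$tt[[v]], state$t[[v]],
                        state$p)
    state$is_topo[[v]] <- (id_v / state$p) / state$max_inf_topo
    state$is[[v]] <- state$lambda * state$is_os[[v]] +
      (1 - state$lambda) * state$is_topo[[v]]
  }
  state
}
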