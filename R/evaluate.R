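#' Count correctly identified essential proteins in a top-k ranking
#'
#' The standard benchmark protocol: take the top `k` candidates of a
#' ranking and count how many appear in the gold-standard essential list.
#' The raw hit count is reported (not a recall: gold proteins absent from
#' the ranked network still sit in the gold set but can never be hit).
#'
#' @param ranking A `ranked_candidates` data frame or a character vector of
#'   protein IDs in rank order.
#' @param gold Non-empty character vector of gold-standard essential
#'   protein IDs.
#' @param k Cutoff, at most the ranking length.
#' @return Integer hit count in `[0, min(k, |gold|)]`.
#' @export
count_correct <- function(ranking, gold, k) {
  ids <- if (inherits(ranking, "ranked_candidates")) ranking$protein
         else as.character(ranking)
  gold <- unique(as.character(gold))
  if (length(gold) == 0) stop("gold essential set is empty")
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  if (k > length(ids)) stop("k = ", k, " exceeds ranking length ", length(ids))
  sum(ids[seq_len(k)] %in% gold)
}

#' Sweep the topology/orthology trade-off
#'
#' Runs the full influence ranking once per lambda value (a single
#' selection at `max(ks)` serves all cutoffs, since the selection sequence
#' for a given lambda is prefix-stable) and tabulates top-k hit counts
#' against the gold list.
#'
#' @param pin A [weighted_pin].
#' @param orthology An [orthology] table.
#' @param gold Gold-standard essential protein IDs.
#' @param lambdas Non-empty numeric vector of lambda values in `[0, 1]`.
#' @param ks Non-empty integer vector of top-k cutoffs.
#' @param p Spread probability.
#' @param tie_break Tie-break policy passed to the ranker.
#' @return An object of class `evaluation_result`: list with `grid`
#'   (data frame `lambda`, `k`, `correct`, `recall`) and `best`
#'   (data frame `k`, `best_lambda`, first argmax per cutoff). The
#'   `recall` column (hits / gold size) is an extension beyond the raw-hit
#'   protocol.
#' @export
lambda_sweep <- function(pin, orthology, gold, lambdas, ks, p = 0.001,
                         tie_break = "lexicographic") {
  stopifnot(length(lambdas) > 0, length(ks) > 0)
  ks <- sort(unique(as.integer(ks)))
  if (max(ks) > length(pin$nodes)) {
    stop("largest k exceeds the number of proteins in the PIN")
  }
  gold <- unique(as.character(gold))
  if (length(gold) == 0) stop("gold essential set is empty")
  rows <- list()
  for (lam in lambdas) {
    params <- imepp_params(lambda = lam, p = p, k = max(ks),
                           tie_break = tie_break)
    ranking <- select_seeds(pin, init_influence(pin, orthology, params),
                            max(ks))
    hits <- vapply(ks, function(k) count_correct(ranking, gold, k),
                   numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(lambda = lam, k = ks, correct = as.integer(hits),
                 recall = hits / length(gold))
  }
  grid <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(ks, function(k) {
    sub <- grid[grid$k == k, ]
    data.frame(k = k, best_lambda = sub$lambda[[which.max(sub$correct)]])
  }))
  structure(list(grid = grid, best = best,
                 params = list(p = p, tie_break = tie_break,
                               n_gold = length(gold))),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("Lambda sweep over", length(unique(x$grid$lambda)), "lambda value(s),",
      length(unique(x$grid$k)), "cutoff(s); gold set size",
      x$params$n_gold, "\n")
  wide <- stats::reshape(x$grid[, c("lambda", "k", "correct")],
                         idvar = "k", timevar = "lambda", direction = "wide")
  names(wide) <- sub("^correct\\.", "lambda=", names(wide))
  print(wide, row.names = FALSE)
  cat("best lambda per k:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}
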