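#' Select ensemble members by recall rank
#'
#' Picks the `k` models with the highest (macro) recall. Ties at the
#' cutoff are broken by a seeded uniform draw among the tied models, and
#' the same draw orders tied members, so rank 1 -- the tiebreaker model --
#' is also randomly chosen among models tied for the best recall.
#'
#' @param recalls Named numeric vector of per-model recall values (names
#'   are model names), or a list of `cyto_report`s (their macro recall is
#'   used).
#' @param k Number of members. Default 3.
#' @param seed Seed for tie breaking.
#' @return An object of class `ensemble_spec`: `members` (names, best
#'   first), `tiebreaker` (= first member), `recalls` (member recalls),
#'   `k`, `seed`.
#' @export
select_members <- function(recalls, k = 3, seed = 1L) {
  if (is.list(recalls) && all(vapply(recalls, inherits, logical(1), "cyto_report")))
    recalls <- vapply(recalls, function(r)
      stats::setNames(r$macro[["recall"]], r$model_name), numeric(1))
  if (is.null(names(recalls)) || any(names(recalls) == ""))
    stop("recalls must be named by model")
  if (k > length(recalls))
    stop("k = ", k, " exceeds the number of models (", length(recalls), ")")
  # seeded jitter ranks: sort by recall desc, random within ties
  ord <- with_seed(seed, order(-recalls, sample(length(recalls))))
  members <- names(recalls)[ord[seq_len(k)]]
  structure(list(members = members, tiebreaker = members[1],
                 recalls = recalls[members], k = k,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("<ensemble_spec>", x$k, "members (best first):\n")
  for (m in x$members)
    cat(sprintf("  %s  recall=%.4f%s\n", m, x$recalls[[m]],
                if (m == x$tiebreaker) "  [tiebreaker]" else ""))
  invisible(x)
}

#' Majority vote of the ensemble members
#'
#' Each sample receives the class predicted by the majority of members.
#' When no majority exists (with three members: all three disagree), the
#' vote of the best-recall member -- the tiebreaker -- prevails. With more
#' than three members the rule generalizes to plurality, ties among the
#' leading classes resolved by the highest-ranked member voting for one of
#' them.
#'
#' @param spec An [select_members()] result.
#' @param predictions Named list of `cyto_predictions`, one per member
#'   (names are model names); all must share the same sample order.
#' @return A `cyto_predictions` object for the ensemble; `scores` holds
#'   the per-class vote fractions.
#' @export
ensemble_vote <- function(spec, predictions) {
  stopifnot(inherits(spec, "ensemble_spec"))
  miss <- setdiff(spec$members, names(predictions))
  if (length(miss) > 0)
    stop("missing predictions for member(s): ", paste(miss, collapse = ", "))
  preds <- predictions[spec$members]               # rank order
  ids <- preds[[1]]$mark_id
  classes <- preds[[1]]$classes
  for (p in preds[-1]) {
    if (!identical(p$mark_id, ids))
      stop("member prediction sets are not aligned on the same sample order")
    if (!identical(p$classes, classes))
      stop("member prediction sets use different class sets")
  }
  votes <- vapply(preds, function(p) p$predicted, character(length(ids)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  decided <- apply(votes, 1, function(v) vote_one(v, classes))
  frac <- t(apply(votes, 1, function(v)
    as.numeric(table(factor(v, levels = classes))) / length(v)))
  colnames(frac) <- classes
  structure(list(model_name = "ensemble", classes = classes, scores = frac,
                 predicted = decided, mark_id = ids),
            class = "cyto_predictions")
}

# Decide one sample: plurality; ties among the leading classes go to the
# highest-ranked member whose vote is one of them (members arrive in rank
# order, so with 3 all-different votes this is member 1's vote).
vote_one <- function(v, classes) {
  tab <- table(factor(v, levels = classes))
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  v[v %in% top][1]
}
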