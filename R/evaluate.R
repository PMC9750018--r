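# Accuracy metrics comparing inferred placements and orders against truth:
# location accuracy, order accuracy over ancestor-descendant pairs,
# adjacent-order accuracy, and credible-set accuracy. All metrics are
# ratios whose numerator/denominator counts are retained so replicates can
# be pooled by summing counts (not by averaging ratios).

mo_ratio <- function(num, den) {
  structure(list(numerator = num, denominator = den,
                 value = if (den > 0) num / den else NA_real_),
            class = "mo_ratio")
}

#' @export
print.mo_ratio <- function(x, ...) {
  cat(x$numerator, "/", x$denominator, "=",
      if (is.na(x$value)) "NA" else format(x$value, digits = 4), "\n")
  invisible(x)
}

#' Pool accuracy ratios across replicates
#'
#' Sums numerators and denominators, matching the convention of evaluating
#' counts across all replicate trees rather than averaging per-replicate
#' ratios.
#' @param ratios list of `mo_ratio` objects.
#' @return a pooled `mo_ratio`.
#' @export
pool_ratios <- function(ratios) {
  mo_ratio(sum(vapply(ratios, function(r) r$numerator, 0)),
           sum(vapply(ratios, function(r) r$denominator, 0)))
}

# relation of two branches: "same", "anc" (a earlier than b), "desc", "side"
branch_relation <- function(tree, a, b) {
  if (a == b) return("same")
  if (is_ancestor_branch(tree, a, b)) return("anc")
  if (is_ancestor_branch(tree, b, a)) return("desc")
  "side"
}

#' Location accuracy
#'
#' Fraction of sites whose inferred (MAP) branch equals the true branch.
#'
#' @param truth,inferred integer vectors of branch ids, same site order.
#' @return an `mo_ratio`.
#' @export
location_accuracy <- function(truth, inferred) {
  stopifnot(length(truth) == length(inferred))
  mo_ratio(sum(truth == inferred), length(truth))
}

#' Order accuracy over mutation pairs
#'
#' The denominator counts all true ordered pairs: pairs of mutations whose
#' true branches are in strict ancestor-descendant relation, plus pairs on
#' the same true branch. A truly ordered pair is inferred correctly iff the
#' inferred branches are in the same strict ancestor-descendant direction
#' (two truly sequential mutations inferred on one common branch count as
#' incorrect). A truly same-branch pair is correct iff inferred on one
#' common branch.
#'
#' @param truth,inferred integer branch ids per site.
#' @param tree the [mo_tree] placements refer to.
#' @return an `mo_ratio`.
#' @export
order_accuracy <- function(truth, inferred, tree) {
  stopifnot(length(truth) == length(inferred))
  num <- 0L; den <- 0L
  I <- length(truth)
  if (I >= 2) for (i in seq_len(I - 1)) for (j in (i + 1):I) {
    rel <- branch_relation(tree, truth[i], truth[j])
    if (rel == "side") next
    den <- den + 1L
    irel <- branch_relation(tree, inferred[i], inferred[j])
    if (rel == "same") {
      if (irel == "same") num <- num + 1L
    } else if (irel == rel) num <- num + 1L
  }
  mo_ratio(num, den)
}

#' Adjacent-order accuracy
#'
#' Restricted to pairs of mutations that truly occurred on adjacent
#' branches (a parent branch and a child branch meeting at a node); such a
#' pair is correct iff the inferred branches are also adjacent with the
#' same direction. True same-branch pairs are included in the denominator
#' (correct iff inferred on one common branch); set
#' `include_same_branch = FALSE` to exclude them.
#'
#' @inheritParams order_accuracy
#' @param include_same_branch count true same-branch pairs (default `TRUE`).
#' @return an `mo_ratio` (`NA` value when no true adjacent pairs exist).
#' @export
adjacent_order_accuracy <- function(truth, inferred, tree,
                                    include_same_branch = TRUE) {
  stopifnot(length(truth) == length(inferred))
  num <- 0L; den <- 0L
  I <- length(truth)
  if (I >= 2) for (i in seq_len(I - 1)) for (j in (i + 1):I) {
    if (truth[i] == truth[j]) {
      if (!include_same_branch) next
      den <- den + 1L
      if (inferred[i] == inferred[j]) num <- num + 1L
    } else if (is_adjacent_child(tree, truth[i], truth[j])) {
      den <- den + 1L
      if (is_adjacent_child(tree, inferred[i], inferred[j])) num <- num + 1L
    } else if (is_adjacent_child(tree, truth[j], truth[i])) {
      den <- den + 1L
      if (is_adjacent_child(tree, inferred[j], inferred[i])) num <- num + 1L
    }
  }
  mo_ratio(num, den)
}

#' Credible-set accuracy
#'
#' Fraction of sites whose true branch lies inside the site's credible set.
#'
#' @param truth integer branch ids per site.
#' @param sets list of [credible_set()] results (or bare id vectors), one
#'   per site.
#' @return an `mo_ratio`.
#' @export
credible_set_accuracy <- function(truth, sets) {
  stopifnot(length(truth) == length(sets))
  hit <- vapply(seq_along(truth), function(i) {
    br <- if (inherits(sets[[i]], "mo_credible_set")) sets[[i]]$branches
          else sets[[i]]
    truth[i] %in% br
  }, TRUE)
  mo_ratio(sum(hit), length(truth))
}

#' Evaluate inferred placements against simulation truth
#'
#' Runs all four metrics for one dataset: MAP location accuracy, order and
#' adjacent-order accuracy of the MAP placements, and 95% (or `theta`-level)
#' credible-set accuracy.
#'
#' @param tree an [mo_tree].
#' @param truth integer vector of true branch ids per site.
#' @param posts list of `mo_posterior` objects per site (failed sites `NULL`
#'   are dropped from all metrics).
#' @param theta credible-set complement level.
#' @return list of `mo_ratio`: `location`, `order`, `adjacent_order`,
#'   `credible_set`.
#' @export
evaluate_placements <- function(tree, truth, posts, theta = 0.05) {
  keep <- !vapply(posts, is.null, TRUE)
  truth <- truth[keep]
  posts <- posts[keep]
  inferred <- vapply(posts, function(p) as.integer(map_location(p)), 0L)
  sets <- lapply(posts, credible_set, theta = theta)
  list(location = location_accuracy(truth, inferred),
       order = order_accuracy(truth, inferred, tree),
       adjacent_order = adjacent_order_accuracy(truth, inferred, tree),
       credible_set = credible_set_accuracy(truth, sets))
}
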