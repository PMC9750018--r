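# Continuous-time Markov models of somatic genotype evolution along the
# tree, and the prior probability that a mutation arises on each branch
# under the one-origin (infinite-sites) constraint. All products over
# branches are computed in log space; normalization uses log-sum-exp.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Transition probability matrices of the genotype process
#'
#' Binary genotypes evolve by an irreversible one-rate process 0 -> 1 with
#' instantaneous rate `lambda` per site, giving `P01(t) = 1 - exp(-lambda t)`.
#' Ternary genotypes (0 homozygous reference, 1 heterozygous, 2 homozygous
#' non-reference) evolve with rates `lambda1` (0 -> 1), `lambda2` (1 -> 2)
#' and a rare direct transition 0 -> 2 at rate `lambda1 * lambda2`. The
#' closed form of `exp(Q t)` has a removable singularity when
#' `lambda2 == lambda1 (1 + lambda2)`, handled by its series limit. With
#' `lambda2 = 0` the ternary model reduces exactly to the binary
#' (infinite-sites diploid) model.
#'
#' @param lambda,lambda1,lambda2 non-negative instantaneous rates per site,
#'   per unit branch length.
#' @param t non-negative branch length (same units).
#' @return a stochastic matrix (2x2 binary, 3x3 ternary), rows = current
#'   state, columns = next state, states in order 0, 1 (, 2).
#' @examples
#' transition_matrix_binary(0.5, 2)[1, 2]  # 1 - exp(-1)
#' @export
transition_matrix_binary <- function(lambda, t) {
  stopifnot(lambda >= 0, t >= 0)
  p00 <- exp(-lambda * t)
  matrix(c(p00, 1 - p00, 0, 1), nrow = 2, byrow = TRUE,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' @rdname transition_matrix_binary
#' @export
transition_matrix_ternary <- function(lambda1, lambda2, t) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, t >= 0)
  a <- lambda1 + lambda1 * lambda2       # total exit rate from state 0
  p00 <- exp(-a * t)
  p11 <- exp(-lambda2 * t)
  d <- lambda2 - a
  p01 <- if (abs(d) < 1e-12 * max(1, a)) {
    lambda1 * t * exp(-a * t)            # removable singularity lambda2 == a
  } else {
    lambda1 * (exp(-a * t) - exp(-lambda2 * t)) / d
  }
  p01 <- max(p01, 0)
  p02 <- max(1 - p00 - p01, 0)
  matrix(c(p00, p01, p02,
           0, p11, 1 - p11,
           0, 0, 1),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("0", "1", "2"), c("0", "1", "2")))
}

# per-branch log transition probabilities for all branches of a tree
branch_logP <- function(tree, mode, rates) {
  tl <- tree$edges$length
  if (mode == "binary") {
    lam <- rates$lambda
    list(l00 = -lam * tl,
         l01 = log(-expm1(-lam * tl)),
         l11 = rep(0, length(tl)))
  } else {
    P <- lapply(tl, function(t)
      transition_matrix_ternary(rates$lambda1, rates$lambda2, t))
    list(l00 = log(vapply(P, function(m) m[1, 1], 0)),
         l01 = log(vapply(P, function(m) m[1, 2], 0)),
         l02 = log(vapply(P, function(m) m[1, 3], 0)),
         l11 = log(vapply(P, function(m) m[2, 2], 0)),
         l12 = log(vapply(P, function(m) m[2, 3], 0)),
         l22 = rep(0, length(tl)))
  }
}

#' Prior probability of mutation placement on each branch
#'
#' Under the one-origin constraint a mutation arises on exactly one branch
#' `x` and is inherited by the whole clade below it. The unnormalized weight
#' of branch `x` is the product of "no mutation" probabilities over branches
#' outside the clade, the acquisition probability on `x`, and "retained"
#' probabilities inside the clade; the weights are normalized over all
#' 2J - 2 branches (and, for ternary genotypes, over the three generating
#' mechanisms: 0 -> 1 only, direct 0 -> 2, and 0 -> 1 on `x` followed by
#' 1 -> 2 on a branch `y` inside `x`'s clade).
#'
#' @param tree an [mo_tree].
#' @param lambda binary-model rate.
#' @param lambda1,lambda2 ternary-model rates.
#' @return an object of class `mo_prior`: list with `mode`, `branch_prob`
#'   (normalized marginal over branches; for ternary, marginal of the
#'   first-transition branch), `log_norm`, and for ternary a `mechanisms`
#'   data frame (`branch`, `mechanism`, `second`, `prob`) summing to 1.
#' @examples
#' tr <- mo_tree("((A:1,B:1):1,C:2);")
#' placement_prior_binary(tr, lambda = 0.3)$branch_prob
#' @export
placement_prior_binary <- function(tree, lambda) {
  lp <- branch_logP(tree, "binary", list(lambda = lambda))
  n <- n_branches(tree)
  logw <- vapply(seq_len(n), function(x) {
    dx <- tree$desc_edges[[x]]
    comp <- setdiff(seq_len(n), c(x, dx))
    sum(lp$l00[comp]) + lp$l01[x] + sum(lp$l11[dx])
  }, 0)
  if (all(!is.finite(logw)))
    stop("placement prior undefined: all branch weights are zero", call. = FALSE)
  ln <- logsumexp(logw)
  p <- exp(logw - ln)
  structure(list(mode = "binary", branch_prob = stats::setNames(p, tree$edges$label),
                 log_weights = logw, log_norm = ln),
            class = "mo_prior")
}

#' @rdname placement_prior_binary
#' @export
placement_prior_ternary <- function(tree, lambda1, lambda2) {
  lp <- branch_logP(tree, "ternary",
                    list(lambda1 = lambda1, lambda2 = lambda2))
  n <- n_branches(tree)
  # clade sums for the two-step mechanism, O(n^2) overall
  s11 <- vapply(seq_len(n), function(x) sum(lp$l11[tree$desc_edges[[x]]]), 0)
  s22 <- vapply(seq_len(n), function(x) sum(lp$l22[tree$desc_edges[[x]]]), 0)
  rows <- vector("list", 3L * n)
  k <- 0L
  for (x in seq_len(n)) {
    dx <- tree$desc_edges[[x]]
    out0 <- sum(lp$l00[setdiff(seq_len(n), c(x, dx))])
    k <- k + 1L
    rows[[k]] <- data.frame(branch = x, mechanism = "0->1", second = NA_integer_,
                            logw = out0 + lp$l01[x] + s11[x])
    k <- k + 1L
    rows[[k]] <- data.frame(branch = x, mechanism = "0->2", second = NA_integer_,
                            logw = out0 + lp$l02[x] + s22[x])
    if (length(dx)) {
      lw <- out0 + lp$l01[x] +
        (s11[x] - lp$l11[dx] - s11[dx]) + lp$l12[dx] + s22[dx]
      k <- k + 1L
      rows[[k]] <- data.frame(branch = x, mechanism = "1->2", second = dx,
                              logw = lw)
    }
  }
  mech <- do.call(rbind, rows[seq_len(k)])
  if (all(!is.finite(mech$logw)))
    stop("placement prior undefined: all branch weights are zero", call. = FALSE)
  ln <- logsumexp(mech$logw)
  mech$prob <- exp(mech$logw - ln)
  bp <- vapply(seq_len(n), function(x) sum(mech$prob[mech$branch == x]), 0)
  structure(list(mode = "ternary",
                 branch_prob = stats::setNames(bp, tree$edges$label),
                 mechanisms = mech, log_norm = ln),
            class = "mo_prior")
}

#' @export
print.mo_prior <- function(x, ...) {
  cat("mo_prior (", x$mode, "), ", length(x$branch_prob), " branches\n", sep = "")
  print(round(x$branch_prob, 4))
  invisible(x)
}

#' True genotypes implied by a placement
#'
#' Given the branch (and, for ternary genotypes, the generating mechanism and
#' possibly the second-transition branch), returns the error-free genotype of
#' every cell: tips inside the clade below the first-transition branch carry
#' the mutation, all others are 0.
#'
#' @param tree an [mo_tree].
#' @param branch branch id of the (first) transition.
#' @param mode `"binary"` or `"ternary"`.
#' @param mechanism for ternary: `"0->1"`, `"0->2"`, or `"1->2"` (the
#'   two-step mechanism; requires `second`).
#' @param second branch id of the 1 -> 2 transition; must lie inside
#'   `branch`'s clade.
#' @return integer vector of genotypes, length J, named by tip label.
#' @export
true_genotypes_for_placement <- function(tree, branch, mode = "binary",
                                         mechanism = "0->1", second = NULL) {
  g <- stats::setNames(integer(tree$J), tree$tips)
  carriers <- clade_tip_idx(tree, branch)
  if (mode == "binary") {
    g[carriers] <- 1L
    return(g)
  }
  if (mechanism == "0->1") {
    g[carriers] <- 1L
  } else if (mechanism == "0->2") {
    g[carriers] <- 2L
  } else if (mechanism == "1->2") {
    if (is.null(second) || !is_ancestor_branch(tree, branch, second))
      stop("second-transition branch must be a strict descendant of the first",
           call. = FALSE)
    g[carriers] <- 1L
    g[clade_tip_idx(tree, second)] <- 2L
  } else stop("unknown mechanism: ", mechanism, call. = FALSE)
  g
}
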