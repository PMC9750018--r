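# Posterior distribution of each mutation's branch placement, MAP
# estimates, credible sets, pairwise/joint order distributions, and Monte
# Carlo integration over parameter priors.

# numerator (log prior-prob + log likelihood) over the branches of `ptree`
# for one site; s_kept is aligned with ptree$tips.
site_log_numerator <- function(ptree, s_kept, mode, alpha, beta, rates,
                               weights = NULL) {
  L <- cell_obs_loglik(s_kept, alpha, beta, mode, weights)
  n <- n_branches(ptree)
  if (mode == "binary") {
    prior <- placement_prior_binary(ptree, rates$lambda)
    lnum <- vapply(seq_len(n), function(x) {
      g <- true_genotypes_for_placement(ptree, x, "binary")
      log(prior$branch_prob[x]) + sum(L[cbind(seq_along(g), g + 1L)])
    }, 0)
    list(lnum = lnum, mech = NULL)
  } else {
    prior <- placement_prior_ternary(ptree, rates$lambda1, rates$lambda2)
    mech <- prior$mechanisms
    mech$loglik <- vapply(seq_len(nrow(mech)), function(r) {
      g <- true_genotypes_for_placement(ptree, mech$branch[r], "ternary",
                                        mech$mechanism[r],
                                        if (is.na(mech$second[r])) NULL
                                        else mech$second[r])
      sum(L[cbind(seq_along(g), g + 1L)])
    }, 0)
    mech$lnum <- log(mech$prob) + mech$loglik
    lnum <- vapply(seq_len(n), function(x) {
      v <- mech$lnum[mech$branch == x]
      if (length(v)) logsumexp(v) else -Inf
    }, 0)
    list(lnum = lnum, mech = mech)
  }
}

# distribute probability mass on projected branches back to original
# branches, proportionally to original branch lengths along each merged path
# (uniform over the path when all lengths are zero).
backmap_probs <- function(tree, proj, p_sub) {
  out <- stats::setNames(numeric(n_branches(tree)), tree$edges$label)
  for (sb in seq_along(p_sub)) {
    path <- proj$branch_map[[sb]]
    len <- tree$edges$length[path]
    w <- if (sum(len) > 0) len / sum(len) else rep(1 / length(path), length(path))
    out[path] <- out[path] + p_sub[sb] * w
  }
  out
}

#' Posterior distribution of a mutation's branch placement
#'
#' Combines the placement prior (one-origin genotype model) with the
#' single-cell error-model likelihood of the observed states, by Bayes'
#' theorem, into a normalized posterior over the 2J - 2 branches. Cells with
#' missing data are excluded by projecting the tree onto the observed cells;
#' posterior mass on a merged projected branch is distributed over its
#' original-branch path proportionally to the original branch lengths.
#'
#' @param tree an [mo_tree].
#' @param s_row observed states for all J cells (integer: 0/1/2, `NA`
#'   missing, `-1L` ambiguous), optionally named by tip label.
#' @param mode `"binary"` or `"ternary"`.
#' @param alpha,beta error probabilities, scalar or per-cell (length J).
#' @param lambda binary transition rate; `lambda1`, `lambda2` ternary rates.
#' @param weights optional list (per cell) of ambiguity weight vectors.
#' @param site optional site label carried into the result.
#' @return an object of class `mo_posterior`: `prob` (named vector over the
#'   original branches, summing to 1), `log_evidence`, `mechanisms` (ternary
#'   mechanism table on the projected tree, or `NULL`), `kept_tips`, `mode`.
#' @examples
#' tr <- mo_tree("((A:1,B:1):1,C:2);")
#' placement_posterior(tr, c(A = 1, B = 1, C = 0), alpha = 0.05, beta = 0.1,
#'                     lambda = 0.1)$prob
#' @export
placement_posterior <- function(tree, s_row, mode = c("binary", "ternary"),
                                alpha, beta, lambda = NULL, lambda1 = NULL,
                                lambda2 = NULL, weights = NULL, site = NULL) {
  mode <- match.arg(mode)
  rates <- check_rates(mode, lambda, lambda1, lambda2)
  s_row <- align_site_row(tree, s_row)
  miss <- tree$tips[is.na(s_row)]
  proj <- project_subtree(tree, miss)
  idx <- match(proj$tree$tips, tree$tips)
  a <- rep_len(alpha, tree$J)[idx]
  b <- rep_len(beta, tree$J)[idx]
  w <- if (is.null(weights)) NULL else weights[idx]
  num <- site_log_numerator(proj$tree, s_row[idx], mode, a, b, rates, w)
  if (all(!is.finite(num$lnum)))
    stop("inference failure: zero posterior numerator on every branch",
         call. = FALSE)
  le <- logsumexp(num$lnum)
  p_sub <- exp(num$lnum - le)
  prob <- backmap_probs(tree, proj, p_sub)
  mech <- num$mech
  if (!is.null(mech)) {
    mech$posterior <- exp(mech$lnum - le)
    mech <- mech[, c("branch", "mechanism", "second", "posterior")]
  }
  structure(list(prob = prob, log_evidence = le, mechanisms = mech,
                 kept_tips = proj$kept_tips, mode = mode, site = site),
            class = "mo_posterior")
}

check_rates <- function(mode, lambda, lambda1, lambda2) {
  if (mode == "binary") {
    if (is.null(lambda)) stop("binary mode requires `lambda`", call. = FALSE)
    list(lambda = lambda)
  } else {
    if (is.null(lambda1) || is.null(lambda2))
      stop("ternary mode requires `lambda1` and `lambda2`", call. = FALSE)
    list(lambda1 = lambda1, lambda2 = lambda2)
  }
}

align_site_row <- function(tree, s_row) {
  if (!is.null(names(s_row))) {
    if (!setequal(names(s_row), tree$tips))
      stop("site row names do not match tree tips; offending labels: ",
           paste(setdiff(names(s_row), tree$tips), collapse = ", "),
           call. = FALSE)
    s_row <- s_row[tree$tips]
  }
  if (length(s_row) != tree$J)
    stop("site row has ", length(s_row), " cells; tree has ", tree$J,
         call. = FALSE)
  as.integer(s_row)
}

#' @export
print.mo_posterior <- function(x, ...) {
  cat("mo_posterior (", x$mode, ")",
      if (!is.null(x$site)) paste0(" site ", x$site), "\n", sep = "")
  print(round(sort(x$prob, decreasing = TRUE)[1:min(5, length(x$prob))], 4))
  invisible(x)
}

#' Posteriors for every site of a mutation matrix
#'
#' @inheritParams placement_posterior
#' @param S observed matrix (sites x cells) as from [read_mutation_matrix()];
#'   column names must match the tree tips.
#' @return list with `posteriors` (per site, `NULL` on failure) and
#'   `failures` (character messages per failed site).
#' @export
mutation_posteriors <- function(tree, S, mode = c("binary", "ternary"),
                                alpha, beta, lambda = NULL, lambda1 = NULL,
                                lambda2 = NULL, weights = NULL) {
  mode <- match.arg(mode)
  if (!is.null(colnames(S)) && !setequal(colnames(S), tree$tips))
    stop("matrix cells do not match tree tips; offending labels: ",
         paste(union(setdiff(colnames(S), tree$tips),
                     setdiff(tree$tips, colnames(S))), collapse = ", "),
         call. = FALSE)
  sites <- rownames(S) %||% paste0("s", seq_len(nrow(S)))
  posts <- vector("list", nrow(S))
  fails <- character(0)
  for (i in seq_len(nrow(S))) {
    row <- S[i, ]
    if (!is.null(colnames(S))) names(row) <- colnames(S)
    posts[i] <- list(tryCatch(
      placement_posterior(tree, row, mode, alpha = alpha, beta = beta,
                          lambda = lambda, lambda1 = lambda1,
                          lambda2 = lambda2, weights = weights,
                          site = sites[i]),
      error = function(e) {
        fails <<- c(fails, paste0(sites[i], ": ", conditionMessage(e)))
        NULL
      }))
  }
  names(posts) <- sites
  list(posteriors = posts, failures = fails)
}

#' MAP branch of a placement posterior
#'
#' Ties are broken deterministically in favor of the smallest branch id and
#' flagged via the `"tie"` attribute.
#'
#' @param post an `mo_posterior` (or bare probability vector).
#' @return integer branch id with attribute `tie`.
#' @export
map_location <- function(post) {
  p <- if (inherits(post, "mo_posterior")) post$prob else post
  m <- max(p)
  ties <- which(p >= m - 1e-12 * max(1, abs(m)))
  structure(ties[1L], tie = length(ties) > 1L)
}

#' Credible set of branches for a mutation placement
#'
#' Branches are added in order of decreasing posterior probability until
#' their cumulative probability reaches `1 - theta`.
#'
#' @param post an `mo_posterior` (or bare probability vector).
#' @param theta complement of the credible level (default 0.05 for a 95% set).
#' @return list of class `mo_credible_set` with `level`, `branches` (ids in
#'   decreasing posterior order), `prob`, `cumulative`.
#' @export
credible_set <- function(post, theta = 0.05) {
  stopifnot(theta >= 0, theta < 1)
  p <- if (inherits(post, "mo_posterior")) post$prob else post
  o <- order(p, decreasing = TRUE)  # stable: ties by increasing branch id
  cs <- cumsum(p[o])
  k <- which(cs >= 1 - theta - 1e-12)[1L]
  if (is.na(k)) k <- length(o)
  k <- max(k, 1L)
  structure(list(level = 1 - theta, branches = o[seq_len(k)],
                 prob = unname(p[o[seq_len(k)]]), cumulative = cs[k]),
            class = "mo_credible_set")
}

#' @export
print.mo_credible_set <- function(x, ...) {
  cat(sprintf("%.0f%% credible set: %d branch(es), cumulative %.4f\n",
              100 * x$level, length(x$branches), x$cumulative))
  invisible(x)
}

#' Pairwise temporal-order probabilities for two mutations
#'
#' The joint placement distribution factorizes over sites, so the
#' probability that mutation i precedes mutation j is the mass of the
#' product distribution on pairs `(x, y)` with `x` a strict ancestor branch
#' of `y`. Mass on the same branch and on incomparable (side) branch pairs
#' is reported separately; the four components sum to 1.
#'
#' @param post_i,post_j `mo_posterior` objects (or probability vectors) over
#'   the same tree.
#' @param tree the [mo_tree] both posteriors refer to.
#' @return named numeric vector `before`, `after`, `same`, `incomparable`.
#' @export
pairwise_order <- function(post_i, post_j, tree) {
  pi_ <- if (inherits(post_i, "mo_posterior")) post_i$prob else post_i
  pj <- if (inherits(post_j, "mo_posterior")) post_j$prob else post_j
  stopifnot(length(pi_) == n_branches(tree), length(pj) == n_branches(tree))
  A <- ancestor_matrix(tree)
  before <- as.numeric(t(pi_) %*% A %*% pj)
  after <- as.numeric(t(pj) %*% A %*% pi_)
  same <- sum(pi_ * pj)
  c(before = before, after = after, same = same,
    incomparable = max(0, 1 - before - after - same))
}

#' Joint MAP branch assignment for a set of mutations
#'
#' Under site independence the joint posterior factorizes, so the joint MAP
#' is the vector of per-site MAP branches and its probability the product of
#' the per-site maxima. Optionally enumerates a `(1 - theta)` credible set
#' of joint assignments in decreasing probability, with a bounded lattice
#' enumeration (the assignment space has `(2J-2)^I` elements).
#'
#' @param posts list of `mo_posterior` objects (one per site).
#' @param theta if non-`NULL`, also build a credible set of joint
#'   assignments at level `1 - theta`.
#' @param cap maximum number of assignments enumerated before the credible
#'   set is reported as truncated.
#' @return list with `assignment` (integer branch ids), `prob`, `ties`
#'   (logical per site), and optionally `credible` (data frame) with
#'   attribute `truncated`.
#' @export
joint_map_order <- function(posts, theta = NULL, cap = 1e6) {
  P <- lapply(posts, function(p) if (inherits(p, "mo_posterior")) p$prob else p)
  maps <- lapply(P, map_location)
  assignment <- vapply(maps, as.integer, 0L)
  ties <- vapply(maps, function(m) isTRUE(attr(m, "tie")), TRUE)
  prob <- prod(vapply(seq_along(P), function(i) P[[i]][assignment[i]], 0))
  out <- list(assignment = assignment, prob = prob, ties = ties)
  if (!is.null(theta)) out$credible <- joint_credible(P, theta, cap)
  out
}

# best-first lattice enumeration of joint assignments by decreasing product
# probability; standard k-best trick: a node may advance coordinate k only
# if all later coordinates sit at rank 1, which enumerates each assignment
# exactly once.
joint_credible <- function(P, theta, cap) {
  I <- length(P)
  ord <- lapply(P, function(p) order(p, decreasing = TRUE))
  sorted <- lapply(seq_len(I), function(i) P[[i]][ord[[i]]])
  lp <- lapply(sorted, function(p) log(p))
  root <- rep(1L, I)
  score <- function(r) sum(vapply(seq_len(I), function(i) lp[[i]][r[i]], 0))
  frontier <- list(list(r = root, s = score(root)))
  seen <- new.env(hash = TRUE)
  assign(paste(root, collapse = ","), TRUE, envir = seen)
  rows <- list(); cum <- 0; count <- 0L; truncated <- FALSE
  while (length(frontier) && cum < 1 - theta) {
    best <- which.max(vapply(frontier, function(nd) nd$s, 0))
    nd <- frontier[[best]]; frontier[[best]] <- NULL
    count <- count + 1L
    if (count > cap) { truncated <- TRUE; break }
    p <- exp(nd$s)
    rows[[length(rows) + 1L]] <- c(vapply(seq_len(I), function(i)
      ord[[i]][nd$r[i]], 0L), p)
    cum <- cum + p
    last_nonone <- {
      nz <- which(nd$r > 1L)
      if (length(nz)) max(nz) else 0L
    }
    for (i in seq_len(I)) {
      if (i < last_nonone) next
      if (nd$r[i] + 1L > length(sorted[[i]])) next
      r2 <- nd$r; r2[i] <- r2[i] + 1L
      key <- paste(r2, collapse = ",")
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        frontier[[length(frontier) + 1L]] <- list(r = r2, s = score(r2))
      }
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c(paste0("site", seq_len(I)), "prob")
  attr(df, "truncated") <- truncated
  attr(df, "cumulative") <- cum
  df
}

#' Prior specification for Monte Carlo integration
#'
#' Each parameter is either fixed (a single number) or given a prior:
#' `c(shape1, shape2)` Beta for the error probabilities, `c(shape, scale)`
#' Gamma for the transition rates.
#'
#' @param alpha,beta fixed value or `c(shape1, shape2)` Beta hyperparameters.
#' @param lambda,lambda1,lambda2 fixed value or `c(shape, scale)` Gamma
#'   hyperparameters.
#' @param m number of Monte Carlo draws (default 200).
#' @return object of class `mo_prior_spec`.
#' @export
prior_spec <- function(alpha, beta, lambda = NULL, lambda1 = NULL,
                       lambda2 = NULL, m = 200L) {
  stopifnot(m >= 1)
  spec <- list(alpha = alpha, beta = beta, lambda = lambda,
               lambda1 = lambda1, lambda2 = lambda2, m = as.integer(m))
  for (nm in c("alpha", "beta", "lambda", "lambda1", "lambda2")) {
    v <- spec[[nm]]
    if (!is.null(v) && !(length(v) %in% 1:2 && all(v >= 0)))
      stop("invalid prior for ", nm, call. = FALSE)
  }
  structure(spec, class = "mo_prior_spec")
}

draw_param <- function(v, kind) {
  if (length(v) == 1L) return(v)
  if (kind == "beta") stats::rbeta(1, v[1], v[2])
  else stats::rgamma(1, shape = v[1], scale = v[2])
}

#' Posterior integrated over parameter priors by Monte Carlo
#'
#' Draws the error probabilities and transition rates from their priors `m`
#' times; for each draw computes the unnormalized per-branch numerator
#' (placement prior times likelihood), averages the numerators across draws,
#' and normalizes (Rao-Blackwellized over branches). Deterministic given
#' `seed`. Fixed (degenerate) priors reproduce [placement_posterior()].
#'
#' @inheritParams placement_posterior
#' @param priors an [prior_spec()] object.
#' @param seed integer seed for the draws (`NULL` = use current RNG state).
#' @return an `mo_posterior` (without mechanism table).
#' @export
integrate_posterior <- function(tree, s_row, mode = c("binary", "ternary"),
                                priors, weights = NULL, seed = NULL,
                                site = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(priors, "mo_prior_spec"))
  if (mode == "binary" && is.null(priors$lambda))
    stop("binary mode requires a `lambda` prior", call. = FALSE)
  if (mode == "ternary" && (is.null(priors$lambda1) || is.null(priors$lambda2)))
    stop("ternary mode requires `lambda1` and `lambda2` priors", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  s_row <- align_site_row(tree, s_row)
  miss <- tree$tips[is.na(s_row)]
  proj <- project_subtree(tree, miss)
  idx <- match(proj$tree$tips, tree$tips)
  w <- if (is.null(weights)) NULL else weights[idx]
  M <- priors$m
  lnum <- matrix(-Inf, n_branches(proj$tree), M)
  for (mdx in seq_len(M)) {
    a <- draw_param(priors$alpha, "beta")
    b <- draw_param(priors$beta, "beta")
    rates <- if (mode == "binary") {
      list(lambda = draw_param(priors$lambda, "gamma"))
    } else {
      list(lambda1 = draw_param(priors$lambda1, "gamma"),
           lambda2 = draw_param(priors$lambda2, "gamma"))
    }
    lnum[, mdx] <- site_log_numerator(proj$tree, s_row[idx], mode,
                                      a, b, rates, w)$lnum
  }
  lavg <- apply(lnum, 1, logsumexp) - log(M)
  if (all(!is.finite(lavg)))
    stop("inference failure: zero posterior numerator in every draw",
         call. = FALSE)
  le <- logsumexp(lavg)
  prob <- backmap_probs(tree, proj, exp(lavg - le))
  structure(list(prob = prob, log_evidence = le, mechanisms = NULL,
                 kept_tips = proj$kept_tips, mode = mode, site = site),
            class = "mo_posterior")
}
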