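# Synthetic data generation: random trees (neutral coalescent or recursive
# random split), model-based mutation placement, error injection,
# missing-data masking, mutation loss, and finite-sites histories. All
# randomness goes through R's RNG so a single set.seed() makes a whole
# simulated dataset reproducible.

#' Simulate a random cell phylogeny
#'
#' `"coalescent"` draws a standard neutral coalescent genealogy (exponential
#' waiting times with rate choose(n, 2), optionally rescaled). `"random_split"`
#' recursively splits the tip set uniformly at random and assigns i.i.d.
#' exponential branch lengths (mean 0.2 by default, matching the simulation
#' design the inference is validated against).
#'
#' @param J number of tips (>= 2).
#' @param method `"coalescent"` or `"random_split"`.
#' @param mean_branch_length mean of the exponential branch lengths
#'   (random-split method).
#' @param scale multiplier applied to coalescent branch lengths (a single
#'   knob standing in for demography).
#' @return an [mo_tree] with tips `C1..CJ`.
#' @export
simulate_tree <- function(J, method = c("random_split", "coalescent"),
                          mean_branch_length = 0.2, scale = 1) {
  method <- match.arg(method)
  stopifnot(J >= 2)
  labels <- paste0("C", seq_len(J))
  phy <- if (method == "coalescent") {
    p <- ape::rcoal(J, tip.label = labels)
    p$edge.length <- p$edge.length * scale
    p
  } else {
    ape::rtree(J, rooted = TRUE, tip.label = labels,
               br = function(n) stats::rexp(n, rate = 1 / mean_branch_length))
  }
  mo_tree(phy)
}

#' Simulate mutation placements from the model prior
#'
#' For each of `I` sites, samples the branch (and for ternary genotypes the
#' generating mechanism and possibly the second-transition branch) from the
#' normalized placement prior, then derives the error-free genotype matrix.
#'
#' @param tree an [mo_tree].
#' @param I number of sites.
#' @param mode `"binary"` or `"ternary"`.
#' @param lambda,lambda1,lambda2 transition rates (see
#'   [placement_prior_binary()]).
#' @return list with `placements` (data frame: `site`, `branch`,
#'   `mechanism`, `second`) and `G` (I x J integer genotype matrix, columns
#'   named by tips).
#' @export
simulate_placements <- function(tree, I, mode = c("binary", "ternary"),
                                lambda = NULL, lambda1 = NULL, lambda2 = NULL) {
  mode <- match.arg(mode)
  rates <- check_rates(mode, lambda, lambda1, lambda2)
  G <- matrix(0L, I, tree$J,
              dimnames = list(paste0("s", seq_len(I)), tree$tips))
  if (mode == "binary") {
    prior <- placement_prior_binary(tree, rates$lambda)
    branch <- sample.int(n_branches(tree), I, replace = TRUE,
                         prob = prior$branch_prob)
    pl <- data.frame(site = rownames(G), branch = branch,
                     mechanism = "0->1", second = NA_integer_,
                     stringsAsFactors = FALSE)
    for (i in seq_len(I))
      G[i, ] <- true_genotypes_for_placement(tree, branch[i], "binary")
  } else {
    prior <- placement_prior_ternary(tree, rates$lambda1, rates$lambda2)
    mech <- prior$mechanisms
    ridx <- sample.int(nrow(mech), I, replace = TRUE, prob = mech$prob)
    pl <- data.frame(site = rownames(G), branch = mech$branch[ridx],
                     mechanism = mech$mechanism[ridx],
                     second = mech$second[ridx], stringsAsFactors = FALSE)
    for (i in seq_len(I))
      G[i, ] <- true_genotypes_for_placement(
        tree, pl$branch[i], "ternary", pl$mechanism[i],
        if (is.na(pl$second[i])) NULL else pl$second[i])
  }
  list(placements = pl, G = G)
}

#' Inject sequencing errors into a true genotype matrix
#'
#' Each entry is independently resampled from the row of its error matrix
#' corresponding to the true genotype.
#'
#' @param G integer genotype matrix (sites x cells).
#' @param alpha,beta error probabilities (scalars).
#' @param mode `"binary"` or `"ternary"`.
#' @return integer matrix of observed states, same shape as `G`.
#' @export
inject_errors <- function(G, alpha, beta, mode = c("binary", "ternary")) {
  mode <- match.arg(mode)
  N <- error_matrix(alpha, beta, mode)
  ns <- n_states(mode)
  S <- G
  for (s in 0:(ns - 1L)) {
    idx <- which(G == s)
    if (length(idx))
      S[idx] <- sample.int(ns, length(idx), replace = TRUE,
                           prob = N[s + 1L, ]) - 1L
  }
  S
}

#' Mask a fraction of tips as missing
#'
#' For each site (default) or once globally, selects
#' `round(fraction * J)` tips uniformly at random and sets their entries to
#' `NA` (missing).
#'
#' @param S observed matrix (sites x cells).
#' @param fraction fraction of tips to mask, in `[0, 1)`.
#' @param per_site if `TRUE` (default) tips are drawn independently per
#'   site; otherwise one tip set is masked for all sites.
#' @return `S` with masked entries `NA`; the selection is recorded in
#'   attribute `masked` (list of tip-index vectors per site).
#' @export
mask_missing <- function(S, fraction, per_site = TRUE) {
  stopifnot(fraction >= 0, fraction < 1)
  J <- ncol(S)
  k <- round(fraction * J)
  masked <- vector("list", nrow(S))
  if (k > 0) {
    if (J - k < 2)
      stop("masking would leave fewer than 2 observed cells per site",
           call. = FALSE)
    if (per_site) {
      for (i in seq_len(nrow(S))) {
        m <- sample.int(J, k)
        S[i, m] <- NA_integer_
        masked[[i]] <- sort(m)
      }
    } else {
      m <- sort(sample.int(J, k))
      S[, m] <- NA_integer_
      for (i in seq_len(nrow(S))) masked[[i]] <- m
    }
  }
  attr(S, "masked") <- masked
  S
}

#' Introduce mutation losses
#'
#' Emulates loss of an already-acquired mutation: for each mutation, up to
#' `k` rounds each propose one uniformly drawn branch and accept it with
#' probability `r`; cells descending from an accepted loss branch revert to
#' genotype 0 at that site.
#'
#' @param tree an [mo_tree].
#' @param G integer genotype matrix (sites x cells).
#' @param r per-proposal loss probability.
#' @param k maximum number of losses per mutation.
#' @return list with `G` (modified matrix) and `losses` (data frame: `site`,
#'   `branch`, `accepted`).
#' @export
introduce_losses <- function(tree, G, r, k = 1L) {
  stopifnot(r >= 0, r <= 1, k >= 1)
  n <- n_branches(tree)
  evlog <- list()
  for (i in seq_len(nrow(G))) {
    lost <- 0L
    for (round in seq_len(k)) {
      if (lost >= k) break
      b <- sample.int(n, 1L)
      acc <- stats::runif(1) < r
      evlog[[length(evlog) + 1L]] <- data.frame(site = i, branch = b,
                                            accepted = acc)
      if (acc) {
        G[i, clade_tip_idx(tree, b)] <- 0L
        lost <- lost + 1L
      }
    }
  }
  losses <- if (length(evlog)) do.call(rbind, evlog)
            else data.frame(site = integer(0), branch = integer(0),
                            accepted = logical(0))
  list(G = G, losses = losses)
}

#' Simulate finite-sites binary mutation histories
#'
#' Each site evolves along the tree as a two-state Markov chain (0 -> 1 rate
#' `rate01`, back-mutation 1 -> 0 rate `rate10`), simulated event-by-event
#' (Gillespie) along each branch from root state 0. The full event list is
#' retained so the branch of the first 0 -> 1 event defines the "true
#' location" of each site for accuracy comparisons.
#'
#' @param tree an [mo_tree].
#' @param I number of sites.
#' @param rate01,rate10 transition rates per unit branch length.
#' @return list with `G` (tip genotype matrix), `events` (data frame:
#'   `site`, `branch`, `time`, `from`, `to`), and `first_origin` (branch of
#'   the first 0 -> 1 event per site, `NA` if none).
#' @export
simulate_finite_sites <- function(tree, I, rate01, rate10) {
  stopifnot(rate01 >= 0, rate10 >= 0)
  edges <- tree$edges
  n <- nrow(edges)
  G <- matrix(0L, I, tree$J,
              dimnames = list(paste0("s", seq_len(I)), tree$tips))
  events <- list()
  first_origin <- rep(NA_integer_, I)
  for (i in seq_len(I)) {
    state_at <- integer(max(edges$child, tree$root))
    state_at[tree$root] <- 0L
    for (b in seq_len(n)) {  # preorder: parent state known
      s <- state_at[edges$parent[b]]
      tlen <- edges$length[b]
      pos <- 0
      repeat {
        rate <- if (s == 0L) rate01 else rate10
        if (rate <= 0) break
        pos <- pos + stats::rexp(1, rate)
        if (pos > tlen) break
        s2 <- 1L - s
        events[[length(events) + 1L]] <- data.frame(
          site = i, branch = b, time = pos, from = s, to = s2)
        if (s == 0L && is.na(first_origin[i])) first_origin[i] <- b
        s <- s2
      }
      state_at[edges$child[b]] <- s
      if (edges$is_tip[b]) G[i, edges$child[b]] <- s
    }
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(site = integer(0), branch = integer(0),
                        time = numeric(0), from = integer(0), to = integer(0))
  list(G = G, events = ev, first_origin = first_origin)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining tree simulation, model-based placement,
#' optional mutation loss, error injection, and missing-data masking.
#'
#' @param J,I tips and sites.
#' @param mode `"binary"` or `"ternary"`.
#' @param tree_method passed to [simulate_tree()].
#' @param lambda,lambda1,lambda2 transition rates.
#' @param alpha,beta error probabilities.
#' @param missing fraction of tips masked per site.
#' @param loss_rate,loss_cap mutation-loss parameters (`loss_rate = 0`
#'   disables losses).
#' @param tree optionally, a fixed [mo_tree] to reuse instead of simulating.
#' @return list of class `mo_simdata` with `tree`, `placements`, `G`
#'   (true genotypes, post-loss), `S` (observed), `losses`, `config`.
#' @export
simulate_dataset <- function(J = 10, I = 20, mode = "binary",
                             tree_method = "random_split",
                             lambda = 1e-7, lambda1 = 1e-7, lambda2 = 1e-2,
                             alpha = 0, beta = 0, missing = 0,
                             loss_rate = 0, loss_cap = 1L, tree = NULL) {
  if (is.null(tree)) tree <- simulate_tree(J, tree_method)
  sim <- simulate_placements(tree, I, mode, lambda = lambda,
                             lambda1 = lambda1, lambda2 = lambda2)
  G <- sim$G
  losses <- NULL
  if (loss_rate > 0) {
    lr <- introduce_losses(tree, G, loss_rate, loss_cap)
    G <- lr$G
    losses <- lr$losses
  }
  S <- inject_errors(G, alpha, beta, mode)
  if (missing > 0) S <- mask_missing(S, missing)
  structure(list(tree = tree, placements = sim$placements, G = G, S = S,
                 losses = losses,
                 config = list(J = tree$J, I = I, mode = mode,
                               lambda = lambda, lambda1 = lambda1,
                               lambda2 = lambda2, alpha = alpha, beta = beta,
                               missing = missing, loss_rate = loss_rate,
                               loss_cap = loss_cap)),
            class = "mo_simdata")
}

#' Convert ternary genotypes to binary
#'
#' Maps states 1 and 2 (mutation present) to 1; missing and ambiguous codes
#' are preserved.
#' @param G integer matrix of ternary genotypes/observations.
#' @return integer matrix of binary states.
#' @export
ternary_to_binary <- function(G) {
  G[!is.na(G) & G == 2L] <- 1L
  G
}

#' Named simulation scenarios
#'
#' The scenario grid used for systematic validation: scenarios 1-2 are
#' coalescent trees (10 or 50 tips) with infinite-sites mutations, 3-4 add
#' mutation loss, 5-6 use random-split trees with model-based placement,
#' 7-8 use finite-sites histories, and 9 scales to 500/1000 cells. Error
#' probabilities range over alpha in {0, 0.05, 0.1} and beta in
#' {0, 0.1, 0.25, 0.5}; missing fractions over {0, 0.1, 0.2}.
#'
#' @param name `"scenario1"` .. `"scenario9"`.
#' @return list of scenario parameters (tips, sites grid, tree method,
#'   error/missing grids, loss or finite-sites settings).
#' @export
scenario_config <- function(name) {
  base <- list(alpha = c(0, 0.05, 0.1), beta = c(0, 0.1, 0.25, 0.5),
               missing = c(0, 0.1, 0.2), I = c(20, 40, 80),
               replicates = 100, mode = "binary",
               lambda = 1e-7, lambda1 = 1e-7, lambda2 = 1e-2)
  cfg <- switch(name,
    scenario1 = c(list(J = 10, tree_method = "coalescent"), base),
    scenario2 = c(list(J = 50, tree_method = "coalescent"), base),
    scenario3 = c(list(J = 10, tree_method = "coalescent",
                       loss_rate = c(0.1, 0.2), loss_cap = c(1, 2)), base),
    scenario4 = c(list(J = 50, tree_method = "coalescent",
                       loss_rate = c(0.1, 0.2), loss_cap = c(1, 2)), base),
    scenario5 = c(list(J = 10, tree_method = "random_split"), base),
    scenario6 = c(list(J = 50, tree_method = "random_split"), base),
    scenario7 = c(list(J = 10, tree_method = "coalescent",
                       finite_sites = TRUE, rate01 = 100,
                       rate10 = c(1, 10, 100)), base),
    scenario8 = c(list(J = 50, tree_method = "coalescent",
                       finite_sites = TRUE, rate01 = 100,
                       rate10 = c(1, 10, 100)), base),
    scenario9 = c(list(J = c(500, 1000), tree_method = "coalescent"),
                  utils::modifyList(base, list(I = c(1000, 10000),
                                               alpha = 0.1, beta = 0.1,
                                               replicates = 20))),
    stop("unknown scenario: ", name, call. = FALSE))
  cfg
}
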