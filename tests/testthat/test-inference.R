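test_that("perfect data concentrates the posterior on the true branch", {
  set.seed(20)
  for (k in 1:5) {
    tr <- random_tree(6)
    x <- sample.int(n_branches(tr), 1)
    s <- true_genotypes_for_placement(tr, x, "binary")
    post <- placement_posterior(tr, s, "binary", alpha = 0, beta = 0,
                                lambda = 0.2)
    expect_equal(unname(post$prob[x]), 1, tolerance = 1e-12)
    expect_equal(as.integer(map_location(post)), x)
  }
})

test_that("uninformative data returns the placement prior", {
  tr <- worked_tree()
  s <- rep(-1L, tr$J)  # every cell ambiguous, uniform weights
  names(s) <- tr$tips
  post <- placement_posterior(tr, s, "binary", alpha = 0.1, beta = 0.2,
                              lambda = 0.3)
  prior <- placement_prior_binary(tr, 0.3)
  expect_equal(post$prob, prior$branch_prob, tolerance = 1e-12)
})

test_that("posterior matches the worked prior-times-likelihood product", {
  tr <- worked_tree()
  lam <- 0.3; a <- 0.05; b <- 0.2
  trunk <- trunk_branch(tr)
  s <- c(C1 = 1L, C2 = 0L, C3 = 1L, C4 = 1L, C5 = 0L)  # one dropout
  post <- placement_posterior(tr, s, "binary", alpha = a, beta = b,
                              lambda = lam)
  # manual numerator for the trunk branch
  N <- error_matrix(a, b, "binary")
  prior <- placement_prior_binary(tr, lam)
  num <- prior$branch_prob[trunk] *
    N[2, 2] * N[2, 1] * N[2, 2] * N[2, 2] * N[1, 1]
  expect_equal(unname(post$prob[trunk]), unname(num / exp(post$log_evidence)),
               tolerance = 1e-12)
})

test_that("posterior equals brute-force enumeration (binary and ternary)", {
  set.seed(21)
  for (k in 1:8) {
    tr <- random_tree(sample(3:6, 1))
    a <- runif(1, 0, 0.2); b <- runif(1, 0, 0.3)
    lam <- runif(1, 0.05, 0.8)
    g <- true_genotypes_for_placement(tr, sample.int(n_branches(tr), 1),
                                      "binary")
    s <- as.integer(inject_errors(matrix(g, 1), a, b, "binary"))
    names(s) <- tr$tips
    post <- placement_posterior(tr, s, "binary", alpha = a, beta = b,
                                lambda = lam)
    p_or <- oracle_posterior(tr, "binary", list(lambda = lam), s, a, b)
    expect_lt(max(abs(unname(post$prob) - p_or)), 1e-10)

    l1 <- runif(1, 0.05, 0.5); l2 <- runif(1, 0.05, 0.5)
    st <- sample(0:2, tr$J, replace = TRUE)
    st[st == 2 & runif(tr$J) < 0.3] <- -1L  # some ambiguous entries
    names(st) <- tr$tips
    post3 <- tryCatch(
      placement_posterior(tr, st, "ternary", alpha = a, beta = b,
                          lambda1 = l1, lambda2 = l2),
      error = function(e) NULL)  # some random rows are impossible
    if (!is.null(post3)) {
      p_or3 <- oracle_posterior(tr, "ternary",
                                list(lambda1 = l1, lambda2 = l2), st, a, b)
      expect_lt(max(abs(unname(post3$prob) - p_or3)), 1e-10)
      expect_lt(abs(sum(post3$mechanisms$posterior) - 1), 1e-10)
    }
  }
})

test_that("missing data: posterior is zero off the subtree and normalized", {
  set.seed(22)
  tr <- random_tree(8)
  x <- which(!tr$edges$is_tip)[2]
  s <- true_genotypes_for_placement(tr, x, "binary")
  drop <- sample(tr$tips, 2)
  s[drop] <- NA
  post <- placement_posterior(tr, s, "binary", alpha = 0.05, beta = 0.1,
                              lambda = 0.2)
  expect_lt(abs(sum(post$prob) - 1), 1e-10)
  pr <- project_subtree(tr, drop)
  off <- setdiff(seq_len(n_branches(tr)), unlist(pr$branch_map))
  expect_true(all(post$prob[off] == 0))
})

test_that("inference failure on impossible sites is reported, not fatal", {
  tr <- mo_tree("((A:1,B:1):1,C:2);")
  # all cells mutated cannot arise from a single origin on the rooted tree
  S <- matrix(1L, 1, 3, dimnames = list("s1", c("A", "B", "C")))
  expect_error(placement_posterior(tr, S[1, ], "binary", alpha = 0, beta = 0,
                                   lambda = 0.5), "zero posterior")
  res <- mutation_posteriors(tr, S, "binary", alpha = 0, beta = 0,
                             lambda = 0.5)
  expect_null(res$posteriors[[1]])
  expect_length(res$failures, 1)
})

test_that("MAP tie-breaking picks the lowest branch id and flags the tie", {
  p <- c(0.25, 0.25, 0.4, 0.1)
  m <- map_location(p)
  expect_equal(as.integer(m), 3L)
  expect_false(attr(m, "tie"))
  p2 <- c(0.4, 0.4, 0.2)
  m2 <- map_location(p2)
  expect_equal(as.integer(m2), 1L)
  expect_true(attr(m2, "tie"))
})

test_that("credible sets are greedy minimal prefixes", {
  expect_equal(credible_set(c(0.8, 0.15, 0.05), theta = 0.05)$branches,
               c(1L, 2L))
  # theta -> 1: single top branch
  expect_equal(credible_set(c(0.8, 0.15, 0.05), theta = 0.999)$branches, 1L)
  # uniform over 4: need all 4 at 95%
  expect_length(credible_set(rep(0.25, 4), theta = 0.05)$branches, 4)
  cs <- credible_set(c(0.5, 0.3, 0.15, 0.05), theta = 0.1)
  expect_gte(cs$cumulative, 0.9)
  expect_length(cs$branches, 3)
})

test_that("pairwise order splits mass into before/after/same/incomparable", {
  tr <- worked_tree()
  n <- n_branches(tr)
  trunk <- trunk_branch(tr)
  below <- descendant_branches(tr, trunk)[1]
  pm <- function(b) { v <- numeric(n); v[b] <- 1; v }

  po <- pairwise_order(pm(trunk), pm(below), tr)
  expect_equal(unname(po["before"]), 1)
  # sibling tip branches are incomparable
  sib <- c(branch_by_label(tr, "C1"), branch_by_label(tr, "C2"))
  po2 <- pairwise_order(pm(sib[1]), pm(sib[2]), tr)
  expect_equal(unname(po2["incomparable"]), 1)
  # same branch
  po3 <- pairwise_order(pm(trunk), pm(trunk), tr)
  expect_equal(unname(po3["same"]), 1)

  # mixed posterior: mass 0.6 on an ancestor of the point mass
  outg <- branch_by_label(tr, "C5")
  p_i <- numeric(n); p_i[trunk] <- 0.6; p_i[outg] <- 0.4
  po4 <- pairwise_order(p_i, pm(below), tr)
  expect_equal(unname(po4["before"]), 0.6)
  expect_equal(sum(po4), 1)

  set.seed(23)
  for (k in 1:5) {
    p1 <- runif(n); p1 <- p1 / sum(p1)
    p2 <- runif(n); p2 <- p2 / sum(p2)
    expect_equal(sum(pairwise_order(p1, p2, tr)), 1, tolerance = 1e-12)
  }
})

test_that("joint MAP order factorizes and matches exhaustive enumeration", {
  set.seed(24)
  tr <- random_tree(4)
  n <- n_branches(tr)
  posts <- lapply(1:3, function(i) { p <- runif(n); p / sum(p) })
  jm <- joint_map_order(posts)
  # exhaustive argmax over all (2J-2)^3 assignments
  best <- -Inf; best_a <- NULL
  for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
    pr <- posts[[1]][a] * posts[[2]][b] * posts[[3]][cc]
    if (pr > best) { best <- pr; best_a <- c(a, b, cc) }
  }
  expect_equal(unname(jm$assignment), best_a)
  expect_equal(jm$prob, best)

  # single site reduces to map_location; point masses give probability 1
  one <- joint_map_order(posts[1])
  expect_equal(unname(one$assignment),
               as.integer(map_location(posts[[1]])))
  pm <- lapply(c(2, 5), function(b) { v <- numeric(n); v[b] <- 1; v })
  expect_equal(joint_map_order(pm)$prob, 1)
})

test_that("joint credible set enumerates assignments in decreasing order", {
  set.seed(25)
  tr <- random_tree(3)
  n <- n_branches(tr)
  posts <- lapply(1:2, function(i) { p <- runif(n); p / sum(p) })
  jm <- joint_map_order(posts, theta = 0.1)
  cred <- jm$credible
  expect_false(attr(cred, "truncated"))
  expect_true(all(diff(cred$prob) <= 1e-12))
  expect_gte(attr(cred, "cumulative"), 0.9)
  # probabilities are genuine products
  for (r in seq_len(nrow(cred)))
    expect_equal(cred$prob[r],
                 posts[[1]][cred$site1[r]] * posts[[2]][cred$site2[r]])
  # cap forces truncation flag
  jm2 <- joint_map_order(posts, theta = 0.001, cap = 2)
  expect_true(attr(jm2$credible, "truncated"))
})

test_that("Monte Carlo integration: degenerate priors = fixed parameters", {
  tr <- random_tree(6)
  set.seed(26)
  x <- sample.int(n_branches(tr), 1)
  g <- true_genotypes_for_placement(tr, x, "binary")
  s <- as.integer(inject_errors(matrix(g, 1), 0.05, 0.1, "binary"))
  names(s) <- tr$tips
  fixed <- placement_posterior(tr, s, "binary", alpha = 0.05, beta = 0.1,
                               lambda = 0.2)
  deg <- integrate_posterior(tr, s, "binary",
                             prior_spec(alpha = 0.05, beta = 0.1,
                                        lambda = 0.2, m = 7),
                             seed = 99)
  expect_lt(max(abs(fixed$prob - deg$prob)), 1e-12)
})

test_that("Monte Carlo integration is seed-deterministic and stable", {
  tr <- random_tree(6)
  set.seed(27)
  x <- sample.int(n_branches(tr), 1)
  s <- true_genotypes_for_placement(tr, x, "binary")
  s[2] <- 1L - s[2]
  ps <- prior_spec(alpha = c(2.9, 7.1), beta = c(0.2, 9.8),
                   lambda = c(2, 0.1), m = 50)
  p1 <- integrate_posterior(tr, s, "binary", ps, seed = 42)
  p2 <- integrate_posterior(tr, s, "binary", ps, seed = 42)
  expect_identical(p1$prob, p2$prob)
  p3 <- integrate_posterior(tr, s, "binary", ps, seed = 43)
  expect_false(identical(p1$prob, p3$prob))
  expect_lt(abs(sum(p3$prob) - 1), 1e-10)
})
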