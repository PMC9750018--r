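test_that("simulated trees are rooted bifurcating with 2J-2 branches", {
  set.seed(30)
  expect_equal(n_branches(simulate_tree(2)), 2)
  expect_equal(n_branches(simulate_tree(10)), 18)
  expect_equal(n_branches(simulate_tree(10, "coalescent")), 18)
  for (J in c(3, 7, 25)) {
    expect_equal(n_branches(simulate_tree(J)), 2 * J - 2)
    expect_equal(n_branches(simulate_tree(J, "coalescent")), 2 * J - 2)
  }
})

test_that("random-split branch lengths follow exponential(mean 0.2)", {
  set.seed(31)
  lens <- unlist(lapply(1:300, function(i) simulate_tree(8)$edges$length))
  se <- 0.2 / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 0.2), 3 * se)
})

test_that("simulation is deterministic under a fixed seed", {
  set.seed(77)
  d1 <- simulate_dataset(J = 8, I = 10, alpha = 0.05, beta = 0.1,
                         missing = 0.2, lambda = 1e-7)
  set.seed(77)
  d2 <- simulate_dataset(J = 8, I = 10, alpha = 0.05, beta = 0.1,
                         missing = 0.2, lambda = 1e-7)
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
  expect_identical(d1$placements, d2$placements)
  expect_identical(d1$G, d2$G)
  expect_identical(d1$S, d2$S)
})

test_that("placement sampling matches the model prior (chi-squared GOF)", {
  set.seed(32)
  tr <- random_tree(5)
  prior <- placement_prior_binary(tr, 0.3)$branch_prob
  sim <- simulate_placements(tr, 1e4, "binary", lambda = 0.3)
  counts <- tabulate(sim$placements$branch, nbins = n_branches(tr))
  gof <- suppressWarnings(stats::chisq.test(counts, p = prior))
  expect_gt(gof$p.value, 0.01)
  # genotypes consistent with recorded placements
  for (i in sample(1e4, 20))
    expect_equal(unname(sim$G[i, ]),
                 unname(true_genotypes_for_placement(
                   tr, sim$placements$branch[i], "binary")))
})

test_that("2-tip symmetric tree splits placements 50/50", {
  set.seed(33)
  tr <- mo_tree("(A:1,B:1);")
  sim <- simulate_placements(tr, 1e4, "binary", lambda = 0.3)
  f <- mean(sim$placements$branch == 1)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("ternary placements with lambda2 = 0 never produce state 2", {
  set.seed(34)
  tr <- random_tree(6)
  sim <- simulate_placements(tr, 500, "ternary", lambda1 = 0.1, lambda2 = 0)
  expect_false(any(sim$G == 2L))
  expect_true(all(sim$placements$mechanism == "0->1"))
})

test_that("error injection matches the nominal rates", {
  set.seed(35)
  G <- matrix(rep(0:1, each = 5e4), ncol = 10)
  S <- inject_errors(G, alpha = 0.05, beta = 0.25, "binary")
  fp <- mean(S[G == 0L] == 1L)
  fn <- mean(S[G == 1L] == 0L)
  expect_lt(abs(fp - 0.05), 3 * sqrt(0.05 * 0.95 / 5e4))
  expect_lt(abs(fn - 0.25), 3 * sqrt(0.25 * 0.75 / 5e4))
  # degenerate cases
  expect_identical(inject_errors(G, 0, 0, "binary"), G)
  expect_true(all(inject_errors(matrix(0L, 5, 5), 1, 0, "binary") == 1L))
  # ternary: true 2 never flips
  G2 <- matrix(2L, 10, 10)
  expect_true(all(inject_errors(G2, 0.1, 0.5, "ternary") == 2L))
})

test_that("masking hits the prescribed number of tips, roughly uniformly", {
  set.seed(36)
  S <- matrix(1L, 500, 10)
  Sm <- mask_missing(S, 0.2)
  expect_true(all(rowSums(is.na(Sm)) == 2))
  hits <- colSums(is.na(Sm))
  expect_gt(suppressWarnings(stats::chisq.test(hits)$p.value), 0.01)
  expect_identical(mask_missing(S, 0), S, ignore_attr = TRUE)
  expect_error(mask_missing(matrix(1L, 2, 3), 0.5), "fewer than 2")
})

test_that("mutation loss honors the cap and acceptance rate", {
  set.seed(37)
  tr <- random_tree(8)
  G <- matrix(1L, 2000, 8)
  res <- introduce_losses(tr, G, r = 0.15, k = 1)
  acc <- res$losses$accepted
  expect_lt(abs(mean(acc) - 0.15), 3 * sqrt(0.15 * 0.85 / length(acc)))
  per_site <- tapply(acc, res$losses$site, sum)
  expect_true(all(per_site <= 1))
  res2 <- introduce_losses(tr, G, r = 0.9, k = 2)
  expect_true(all(tapply(res2$losses$accepted, res2$losses$site, sum) <= 2))
  # r = 0: nothing changes
  res0 <- introduce_losses(tr, G, r = 0, k = 2)
  expect_identical(res0$G, G)
  # accepted losses zero out exactly the descendant clade
  hit <- which(res$losses$accepted)[1]
  site <- res$losses$site[hit]; br <- res$losses$branch[hit]
  expect_true(all(res$G[site, clade_tip_idx(tr, br)] == 0L))
})

test_that("finite-sites histories have correct event statistics", {
  set.seed(38)
  # single long branch: event count is Poisson(rate * t); use a 2-tip tree
  tr <- mo_tree("(A:5,B:0.001);")
  fs <- simulate_finite_sites(tr, I = 2000, rate01 = 0.4, rate10 = 0.4)
  bA <- branch_by_label(tr, "A")
  nA <- sum(fs$events$branch == bA)
  lamA <- 0.4 * 5 * 2000
  expect_lt(abs(nA - lamA) / sqrt(lamA), 4)

  # long-branch tip states approach the stationary distribution
  tr2 <- mo_tree("(A:50,B:0.001);")
  fs2 <- simulate_finite_sites(tr2, I = 4000, rate01 = 1, rate10 = 3)
  pstat <- 1 / (1 + 3)
  fA <- mean(fs2$G[, "A"])
  expect_lt(abs(fA - pstat), 3 * sqrt(pstat * (1 - pstat) / 4000))

  # rate01 = 0: no mutations anywhere
  fs0 <- simulate_finite_sites(tr, I = 50, rate01 = 0, rate10 = 1)
  expect_true(all(fs0$G == 0L))
  expect_true(all(is.na(fs0$first_origin)))

  # first_origin is the branch of the first 0->1 event
  ev1 <- fs$events[fs$events$site == fs$events$site[1], ]
  expect_equal(fs$first_origin[ev1$site[1]],
               ev1$branch[ev1$from == 0][1])
})

test_that("ternary-to-binary conversion maps both mutant states to 1", {
  G <- matrix(c(0L, 1L, 2L, NA, -1L, 2L), 2)
  B <- ternary_to_binary(G)
  expect_equal(B[!is.na(G) & G == 2L], c(1L, 1L))
  expect_true(is.na(B[2, 2]))
  expect_equal(B[!is.na(G) & G == -1L], -1L)
})

test_that("perfect-data round trip recovers every placement", {
  set.seed(39)
  sim <- simulate_dataset(J = 10, I = 15, mode = "binary", alpha = 0,
                          beta = 0, missing = 0, lambda = 1e-7)
  res <- mutation_posteriors(sim$tree, sim$S, "binary", alpha = 0, beta = 0,
                             lambda = 1e-7)
  inferred <- vapply(res$posteriors, function(p) as.integer(map_location(p)), 0L)
  expect_equal(unname(inferred), sim$placements$branch)
})

test_that("scenario configurations expose the validation grids", {
  s2 <- scenario_config("scenario2")
  expect_equal(s2$J, 50)
  expect_equal(s2$alpha, c(0, 0.05, 0.1))
  expect_equal(s2$beta, c(0, 0.1, 0.25, 0.5))
  expect_equal(s2$missing, c(0, 0.1, 0.2))
  s7 <- scenario_config("scenario7")
  expect_true(s7$finite_sites)
  expect_equal(s7$rate01, 100)
  expect_equal(s7$rate10, c(1, 10, 100))
  expect_error(scenario_config("scenario99"), "unknown")
})
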