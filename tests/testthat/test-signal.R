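test_that("GLS phylogenetic mean reduces to ordinary moments when C = I", {
  g <- phylo_gls_mean(diag(3), c(1, 2, 3))
  expect_equal(g$ahat, 2)
  expect_equal(g$MSE, 1)
  expect_equal(g$MSE0, 1)
  gc <- phylo_gls_mean(diag(3), c(4, 4, 4))
  expect_equal(gc$MSE, 0)
  expect_equal(gc$MSE0, 0)
})

test_that("GLS mean matches a direct 3x3 linear-algebra solution", {
  C <- phylo_vcv(three_tip())
  x <- c(1, 1, 4)
  g <- phylo_gls_mean(C, x)
  Ci <- solve(C)
  a <- sum(Ci %*% x) / sum(Ci)
  expect_equal(g$ahat, a)
  expect_equal(g$MSE, drop(t(x - a) %*% Ci %*% (x - a)) / 2)
  expect_equal(g$MSE0, sum((x - a)^2) / 2)
  expect_error(phylo_gls_mean(matrix(1, 3, 3), x), "jitter")
})

test_that("Blomberg's K is exactly 1 on a star phylogeny", {
  st <- star_tree(12)
  set.seed(1)
  x <- stats::setNames(rnorm(12), st$tip.label)
  expect_equal(blomberg_k(st, x, n_perm = 99, seed = 1)$K, 1)
})

test_that("K and its permutation p-value behave on structured data", {
  tr <- simulate_yule_tree(80, seed = 3)
  x <- simulate_traits(tr, matrix(1), "BM", seed = 11)[, 1]
  res <- blomberg_k(tr, x, n_perm = 199, seed = 5)
  # independent oracle: phytools implementation of the same statistic
  expect_equal(res$K, as.numeric(phytools::phylosig(tr, x, method = "K")),
               tolerance = 1e-10)
  expect_lt(res$p_random, 0.05)  # BM data on a tree: signal detected
  expect_gte(res$p_random, 1 / 200)  # add-one correction: never zero
  expect_error(blomberg_k(tr, rep(1, 80)), "constant")
})

test_that("lambda ML matches the phytools profile and its LRT calibrates", {
  tr <- simulate_yule_tree(80, seed = 3)
  x <- simulate_traits(tr, matrix(1), "BM", seed = 11)[, 1]
  ours <- pagel_lambda_ml(tr, x)
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(ours$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(ours$logL_lambda, ref$logL, tolerance = 1e-4)
  expect_gte(ours$logL_lambda, ours$logL_zero)
  expect_lt(ours$p_random, 1e-4)
  # destroying structure by shuffling drives lambda toward zero
  set.seed(9)
  xs <- stats::setNames(sample(x), names(x))
  expect_lt(pagel_lambda_ml(tr, xs)$lambda, 0.2)
})

test_that("profile likelihood dominates both boundary values", {
  tr <- simulate_yule_tree(50, seed = 8)
  x <- simulate_traits(tr, matrix(1), "lambda", 0.5, seed = 2)[, 1]
  f <- pagel_lambda_ml(tr, x)
  C <- phylo_vcv(tr)
  ll <- function(l) pestphylo:::.lambda_profile_loglik(
    C, transform_covariance(C, "lambda", l), x)
  expect_gte(f$logL_lambda, ll(0))
  expect_gte(f$logL_lambda, ll(1))
})

test_that("nodal sum of changes matches hand computations", {
  t2 <- read_newick("(A:1,B:1);")
  expect_equal(nodal_sum_of_changes(t2, c(A = 1, B = 0)), 1)
  # symmetric 4-tip tree, states constant within the two root clades:
  # both cherries resolve to their shared state (0 change below them),
  # root value 0.5, so d = |1-0.5| + |0-0.5| = 1
  t4 <- balanced_four()
  expect_equal(nodal_sum_of_changes(t4, c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_error(nodal_sum_of_changes(t4, c(A = 1, B = 1, C = 1, D = 1)),
               "single state")
  expect_error(nodal_sum_of_changes(t4, c(A = 2, B = 1, C = 0, D = 0)), "0/1")
})

test_that("D is near zero for clade-conserved traits with the expected
          p-value pattern", {
  tr <- simulate_yule_tree(64, seed = 14)
  # perfectly conserved: one deep clade carries all the 1s
  kids <- tr$edge[tr$edge[, 1] == 65, 2]
  clade_tips <- if (kids[1] <= 64) kids[1] else
    intersect(ape::prop.part(tr)[[kids[1] - 64]], seq_len(64))
  y <- stats::setNames(as.numeric(seq_len(64) %in% clade_tips), tr$tip.label)
  res <- fritz_purvis_d(tr, y, n_sim = 500, seed = 3)
  expect_lt(res$D, 0.2)          # at or below the Brownian expectation
  expect_lt(res$p_random, 0.01)  # decisively non-random
  expect_gt(res$p_brownian, 0.5) # consistent with Brownian conservatism
  expect_gt(res$p_random, 0)     # add-one correction
})

test_that("D is invariant to relabeling the two states up to resampling
          noise", {
  tr <- simulate_yule_tree(64, seed = 15)
  y <- simulate_binary_threshold(tr, 0.4, seed = 5)
  d1 <- fritz_purvis_d(tr, y, n_sim = 800, seed = 7)$D
  d2 <- fritz_purvis_d(tr, 1 - y, n_sim = 800, seed = 8)$D
  expect_lt(abs(d1 - d2), 0.35)
})

test_that("degenerate inputs to D are rejected", {
  tr <- simulate_yule_tree(10, seed = 1)
  expect_error(fritz_purvis_d(tr, rep(1, 10)), "single state")
  expect_error(fritz_purvis_d(tr, simulate_binary_threshold(tr, 0.5, 1),
                              n_sim = 100), "at least 500")
})

test_that("multi-level traits binarize against the modal level", {
  x <- c(a = "leaf", b = "leaf", c = "stem", d = "soil")
  y <- binarize_vs_modal(x)
  expect_equal(unname(y), c(1, 1, 0, 0), ignore_attr = TRUE)
  expect_equal(attr(y, "modal_level"), "leaf")
})
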