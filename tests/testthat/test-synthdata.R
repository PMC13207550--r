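test_that("Yule trees are unit height, labeled, and seed-reproducible", {
  t2 <- simulate_yule_tree(2, seed = 1)
  expect_length(t2$tip.label, 2)
  expect_equal(tree_height(t2), 1)
  tr <- simulate_yule_tree(129, seed = 5)
  expect_length(tr$tip.label, 129)
  expect_true(is_ultrametric_tol(tr))
  expect_identical(tr$tip.label[1], "sp0001")
  expect_true(ape::all.equal.phylo(tr, simulate_yule_tree(129, seed = 5)))
  expect_false(ape::all.equal.phylo(tr, simulate_yule_tree(129, seed = 6)))
})

test_that("trait simulation reproduces the requested covariance structure", {
  tr <- read_newick("((A:0.5,B:0.5):0.5,C:1);")
  R <- matrix(c(1, 0.7, 0.7, 1), 2)
  # Monte-Carlo over replicate draws: cov(Y_A1, Y_B1) -> R[1,1] * C[A,B]
  Ys <- sapply(1:400, function(i)
    simulate_traits(tr, R, "BM", seed = i)[c(1, 2), 1])
  expect_equal(stats::cov(Ys[1, ], Ys[2, ]), 0.5, tolerance = 0.12)
  # cross-trait, same species: R[1,2] * C[A,A]
  Ys2 <- sapply(1:400, function(i) simulate_traits(tr, R, "BM", seed = i)[1, ])
  expect_equal(stats::cov(Ys2[1, ], Ys2[2, ]), 0.7, tolerance = 0.12)
  # lambda = 0: no cross-species covariance
  Ys3 <- sapply(1:400, function(i)
    simulate_traits(tr, R, "lambda", 0, seed = i)[c(1, 2), 1])
  expect_lt(abs(stats::cov(Ys3[1, ], Ys3[2, ])), 0.12)
})

test_that("threshold simulation fixes the count of ones", {
  tr <- simulate_yule_tree(129, seed = 8)
  y <- simulate_binary_threshold(tr, 0.295, seed = 2)
  expect_equal(sum(y), 38) # ceiling(0.295 * 129)
  expect_identical(y, simulate_binary_threshold(tr, 0.295, seed = 2))
  expect_error(simulate_binary_threshold(tr, 1.2, 1), "prevalence")
})

test_that("invasion simulation calibrates its intercept to the target
          prevalence", {
  tr <- simulate_yule_tree(300, seed = 9)
  X <- matrix(rnorm(300), dimnames = list(tr$tip.label, "x"))
  sim <- simulate_invasion(X, rep("g", 300), beta = 0.5, sigma_phylo = 1,
                           sigma_guild = 0, tree = tr, seed = 3,
                           target_prevalence = 0.295)
  expect_lt(abs(mean(sim$prob) - 0.295), 0.02)
  # neutral settings give a prevalence near one half
  st <- star_tree(1000)
  X0 <- matrix(rnorm(1000), dimnames = list(st$tip.label, "x"))
  sim0 <- simulate_invasion(X0, rep("g", 1000), beta = 0, sigma_phylo = 0,
                            sigma_guild = 0, tree = st, seed = 4, alpha = 0)
  expect_lt(abs(mean(sim0$y) - 0.5), 0.05)
})

test_that("a strong positive coefficient shows up as monotone risk in
          trait deciles", {
  st <- star_tree(1000)
  set.seed(10)
  X <- matrix(rnorm(1000), dimnames = list(st$tip.label, "x"))
  sim <- simulate_invasion(X, rep("g", 1000), beta = 2, sigma_phylo = 0,
                           sigma_guild = 0, tree = st, seed = 5, alpha = 0)
  dec <- cut(X[, 1], stats::quantile(X[, 1], 0:10 / 10), include.lowest = TRUE)
  rates <- tapply(sim$y, dec, mean)
  expect_gt(rates[10], rates[1])
  expect_gt(stats::cor(seq_len(10), as.numeric(rates), method = "spearman"),
            0.8)
})

test_that("missingness masking is MCAR at the requested rate with a floor
          of observed cells", {
  Y <- matrix(rnorm(129 * 7), 129, 7)
  expect_identical(apply_missingness(Y, 0, seed = 1), Y)
  Ym <- apply_missingness(Y, 0.0908, seed = 1)
  expect_identical(Ym, apply_missingness(Y, 0.0908, seed = 1))
  n_missing <- sum(is.na(Ym))
  expect_lt(abs(n_missing - 129 * 7 * 0.0908), 3 * sqrt(129 * 7 * 0.0908))
  # heavy masking still leaves 5 observed per trait
  Yh <- apply_missingness(matrix(rnorm(10 * 3), 10, 3), 0.5, seed = 2)
  expect_true(all(colSums(!is.na(Yh)) >= 5))
  expect_error(apply_missingness(Y, 0.9, 1), "0.5")
})

test_that("the study bundle matches the emulated assemblage structure", {
  sim <- simulate_study(seed = 77)
  expect_length(sim$tree$tip.label, 129)
  expect_equal(nlevels(sim$guild), 7)
  expect_equal(length(unique(sim$taxonomy$order)), 7)
  expect_equal(ncol(sim$traits$continuous), 7)
  expect_equal(ncol(sim$traits$categorical), 3)
  # invasion prevalence near the 29.5% target
  expect_lt(abs(mean(sim$invasion) - 0.295), 0.1)
  # missingness near 9.08% over continuous cells
  expect_lt(abs(mean(is.na(sim$traits$continuous)) - 0.0908), 0.03)
  # strong phylogenetic signal in the generated traits
  x <- sim$truth$continuous[, "body_length"]
  expect_gt(pagel_lambda_ml(sim$tree, x)$lambda, 0.6)
  # reproducibility
  sim2 <- simulate_study(seed = 77)
  expect_identical(sim$invasion, sim2$invasion)
  expect_identical(sim$traits$continuous, sim2$traits$continuous)
})
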