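toy_setup <- function(miss = TRUE) {
  tr <- read_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  R <- matrix(c(1, 0.5, 0.5, 2), 2,
              dimnames = list(c("t1", "t2"), c("t1", "t2")))
  mu <- c(0.3, -0.2)
  Y <- simulate_traits(tr, R, "BM", seed = 2)
  if (miss) Y[2, 1] <- NA
  list(tree = tr, C = phylo_vcv(tr), R = R, mu = mu, Y = Y)
}

test_that("masked log-likelihood equals the dense joint-Gaussian oracle", {
  s <- toy_setup()
  expect_equal(mvbm_loglik(s$C, s$Y, s$R, s$mu),
               dense_mvn_loglik(s$C, s$Y, s$R, s$mu), tolerance = 1e-6)
  # several masks on the 4-taxon, 2-trait toy
  for (cells in list(c(1, 6), c(3, 4, 8), 7)) {
    Y2 <- toy_setup(miss = FALSE)$Y
    Y2[cells] <- NA
    expect_equal(mvbm_loglik(s$C, Y2, s$R, s$mu),
                 dense_mvn_loglik(s$C, Y2, s$R, s$mu), tolerance = 1e-6)
  }
})

test_that("complete-data likelihood reduces to known special cases", {
  s <- toy_setup(miss = FALSE)
  # p = 1: univariate phylogenetic GLS normal likelihood
  x <- s$Y[, 1, drop = FALSE]
  sig2 <- 0.8
  ll <- mvbm_loglik(s$C, x, matrix(sig2), 0.1)
  r <- x[, 1] - 0.1
  expect_equal(ll, -0.5 * (4 * log(2 * pi) +
                             determinant(sig2 * s$C)$modulus[1] +
                             drop(t(r) %*% solve(sig2 * s$C, r))))
  # C = I: iid multivariate normal over species
  ll2 <- mvbm_loglik(diag(4), s$Y, s$R, s$mu)
  acc <- sum(apply(s$Y, 1, function(row) {
    r <- row - s$mu
    -0.5 * (2 * log(2 * pi) + determinant(s$R)$modulus[1] +
              drop(t(r) %*% solve(s$R, r)))
  }))
  expect_equal(ll2, acc)
  expect_error(mvbm_loglik(s$C, s$Y, matrix(c(1, 2, 2, 1), 2), s$mu),
               "positive definite")
})

test_that("conditional-mean imputation equals the partitioned-Gaussian
          oracle", {
  s <- toy_setup()
  fit <- structure(list(model = "BM", R = s$R, mu = s$mu,
                        transform_param = NULL, traits = colnames(s$Y),
                        species = rownames(s$Y)), class = "evomodel_fit")
  imp <- impute_missing(fit, s$tree, s$Y)
  oracle <- dense_conditional(s$C, s$Y, s$R, s$mu)
  expect_equal(imp$completed[2, 1], oracle$mean, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(imp$imputation_variance[2, 1], oracle$var, tolerance = 1e-6,
               ignore_attr = TRUE)
  # observed cells untouched
  obs <- !is.na(s$Y)
  expect_identical(imp$completed[obs], s$Y[obs])
  expect_true(all(imp$imputation_variance[obs] %in% NA))
})

test_that("imputation on a star tree with one trait is mean imputation", {
  st <- star_tree(6)
  Y <- matrix(c(1, 2, 3, 4, 5, NA), dimnames = list(st$tip.label, "t"))
  fit <- fit_evomodel(st, Y, "BM")
  imp <- impute_missing(fit, st, Y)
  expect_equal(unname(imp$completed[6, 1]), 3)
})

test_that("ML fit recovers parameters and AIC bookkeeping is consistent", {
  tr <- simulate_yule_tree(120, seed = 6)
  R <- matrix(c(1, 0.6, 0.6, 1.5), 2)
  Y <- simulate_traits(tr, R, "BM", mu = c(2, -1), seed = 7)
  fit <- fit_evomodel(tr, Y, "BM")
  expect_equal(fit$n_par, 2 + 3)
  expect_equal(fit$AIC, 2 * fit$n_par - 2 * fit$logL)
  expect_equal(fit$mu, c(2, -1), tolerance = 0.8, ignore_attr = TRUE)
  expect_lt(max(abs(fit$R - R)), 0.6)
  # AIC ordering invariant to shifting all trait means
  fit2 <- fit_evomodel(tr, Y + 100, "BM")
  expect_equal(fit2$AIC, fit$AIC, tolerance = 1e-4)
})

test_that("the lambda transform parameter is recovered from lambda data", {
  tr <- simulate_yule_tree(150, seed = 16)
  Y <- simulate_traits(tr, diag(2), "lambda", 0.6, seed = 17)
  fit <- fit_evomodel(tr, Y, "lambda")
  expect_lt(abs(fit$transform_param - 0.6), 0.25)
  expect_gte(fit$logL, fit_evomodel(tr, Y, "BM")$logL - 1e-6)
})

test_that("trait-covariance estimates improve with sample size", {
  # nested design: the 50-tip problem is a subsample of the same 200-tip
  # realization, and errors are averaged over three trait draws per tree
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  wins <- 0
  for (i in 1:8) {
    tr <- simulate_yule_tree(200, seed = 300 + i)
    sub <- ape::keep.tip(tr, tr$tip.label[1:50])
    e_small <- e_full <- 0
    for (j in 1:3) {
      Y <- simulate_traits(tr, R, "BM", seed = 400 + 10 * i + j)
      e_small <- e_small +
        sqrt(sum((fit_evomodel(sub, Y[sub$tip.label, ], "BM")$R - R)^2))
      e_full <- e_full + sqrt(sum((fit_evomodel(tr, Y, "BM")$R - R)^2))
    }
    if (e_full < e_small) wins <- wins + 1
  }
  expect_gte(wins, 7) # decreasing error in >= 80% of replicate pairs
})

test_that("imputation with missing data beats trait-mean imputation", {
  tr <- simulate_yule_tree(80, seed = 26)
  R <- 0.5 * (diag(3) + 0.4)
  better <- 0
  for (i in 1:5) {
    Y <- simulate_traits(tr, R, "BM", seed = 500 + i)
    Ym <- apply_missingness(Y, 0.1, seed = 600 + i)
    hidden <- is.na(Ym) & !is.na(Y)
    fit <- fit_evomodel(tr, Ym, "BM")
    imp <- impute_missing(fit, tr, Ym)
    rmse_phylo <- sqrt(mean((imp$completed[hidden] - Y[hidden])^2))
    means <- matrix(colMeans(Ym, na.rm = TRUE), nrow(Y), ncol(Y), byrow = TRUE)
    rmse_mean <- sqrt(mean((means[hidden] - Y[hidden])^2))
    if (rmse_phylo < rmse_mean) better <- better + 1
  }
  expect_gte(better, 4)
})

test_that("fits demand enough observed species per trait", {
  tr <- simulate_yule_tree(10, seed = 1)
  Y <- simulate_traits(tr, diag(1), "BM", seed = 1)
  Y[1:7, 1] <- NA
  expect_error(fit_evomodel(tr, Y, "BM"), "at least 5")
})
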