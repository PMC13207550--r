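# small, fast MCMC budgets throughout; the full default budget is exercised
# by the acceptance suite

small_spec <- function(seed = 51, n = 60) {
  sim <- simulate_study(n_species = n, n_orders = 4, n_guilds = 4,
                        missing_rate = 0, seed = seed)
  build_design(sim$truth$continuous, sim$truth$categorical, sim$guild,
               sim$invasion, phylo_vcv(sim$tree, standardize = TRUE),
               mcmc = list(chains = 2, iter = 600, warmup = 300, seed = 1))
}

test_that("design assembly standardizes, dummy-codes and orders columns", {
  sim <- simulate_study(n_species = 50, missing_rate = 0, seed = 52)
  spec <- build_design(sim$truth$continuous, sim$truth$categorical,
                       sim$guild, sim$invasion,
                       phylo_vcv(sim$tree, standardize = TRUE))
  # 7 continuous + (3-1) + (2-1) + (2-1) dummies = 11 columns
  expect_equal(ncol(spec$X), 11)
  expect_identical(colnames(spec$X)[1:7], colnames(sim$truth$continuous))
  expect_lt(max(abs(colMeans(spec$X[, 1:7]))), 1e-12)
  expect_equal(unname(apply(spec$X[, 1:7], 2, sd)), rep(1, 7))
  expect_equal(max(diag(spec$A)), 1)
  # dummy columns are named trait.level against the lexicographic reference
  expect_true("reproductive_mode.sexual" %in% colnames(spec$X))
})

test_that("rank-deficient designs are rejected with the aliased column named", {
  sim <- simulate_study(n_species = 40, missing_rate = 0, seed = 53)
  X <- sim$truth$continuous
  X <- cbind(X, dup = X[, "fecundity"])
  expect_error(build_design(X, NULL, sim$guild, sim$invasion,
                            phylo_vcv(sim$tree, standardize = TRUE)),
               "rank deficient")
})

test_that("with a symmetric balanced outcome the intercept centers at 0.5
          probability", {
  st <- star_tree(40)
  set.seed(54)
  X <- matrix(rnorm(40), dimnames = list(st$tip.label, "x"))
  y <- rep(c(0, 1), 20)
  spec <- build_design(X, NULL, guild = rep("g1", 40), invasion = y,
                       A = phylo_vcv(st, standardize = TRUE),
                       mcmc = list(chains = 2, iter = 1000, warmup = 500,
                                   seed = 3))
  fit <- fit_bernoulli_mixed(spec, include_phylo = FALSE)
  p <- mean(plogis(posterior_draws(fit, "alpha")))
  expect_lt(abs(p - 0.5), 0.08)
})

test_that("the PGLMM with sigma_phylo fixed at 0 matches the GLMM", {
  spec <- small_spec()
  f0 <- fit_bernoulli_mixed(spec, include_phylo = TRUE, sigma_phylo_fixed = 0,
                            iter = 1200, warmup = 600)
  f1 <- fit_bernoulli_mixed(spec, include_phylo = FALSE,
                            iter = 1200, warmup = 600)
  b0 <- colMeans(posterior_draws(f0, paste0("b_", colnames(spec$X))))
  b1 <- colMeans(posterior_draws(f1, paste0("b_", colnames(spec$X))))
  expect_lt(max(abs(b0 - b1)), 0.15)
  expect_identical(f1$model_kind, "GLMM")
  expect_false("sigma_phylo" %in% f1$par_names)
})

test_that("draw bookkeeping and convergence reporting are wired through", {
  spec <- small_spec()
  fit <- fit_bernoulli_mixed(spec)
  expect_equal(nrow(posterior_draws(fit)), 2 * 300)
  rep <- convergence_report(fit)
  expect_s3_class(rep, "convergence_report")
  expect_true(all(c("rhat", "ess_bulk", "ess_tail") %in% names(rep$table)))
  expect_true(all(rep$table$rhat >= 1 | is.na(rep$table$rhat)))
  f1 <- fit_bernoulli_mixed(spec, chains = 1)
  expect_error(convergence_report(f1), "two chains")
})

test_that("an over-short run fails the convergence contract loudly", {
  spec <- small_spec()
  expect_error(fit_bernoulli_mixed(spec, iter = 40, warmup = 20,
                                   check_convergence = TRUE),
               "convergence contract")
})

test_that("variance decomposition identities hold per draw", {
  spec <- small_spec()
  fit <- fit_bernoulli_mixed(spec)
  vd <- variance_decomposition(fit)
  pd <- vd$per_draw
  shares <- pd[, c("share_fixed", "share_phylo", "share_guild", "share_resid")]
  expect_equal(unname(rowSums(shares)), rep(1, nrow(pd)))
  expect_true(all(pd[, "R2_marginal"] <= pd[, "R2_conditional"]))
  expect_true(all(pd[, "R2_conditional"] <= 1 & pd[, "R2_marginal"] >= 0))
  expect_equal(vd$var_resid, 3.2899, tolerance = 1e-4)
  # GLMM variant carries no phylogenetic component
  vg <- variance_decomposition(fit_bernoulli_mixed(spec, include_phylo = FALSE))
  expect_true(all(vg$per_draw[, "share_phylo"] == 0))
})

test_that("posterior summaries expose 80% and 95% intervals", {
  fit <- fit_bernoulli_mixed(small_spec())
  ps <- posterior_summary(fit)
  expect_true(all(c("q10", "q90", "q2.5", "q97.5") %in% names(ps)))
  expect_true(all(ps$q10 <= ps$q90))
  expect_true(all(ps$q2.5 <= ps$q10))
})
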