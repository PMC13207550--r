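make_table <- function() {
  cont <- cbind(size = c(exp(1), 1, 4, NA, 2),
                eggs = c(10, 20, NA, 40, 0))
  cat_df <- data.frame(
    substrate = c("leaf", "leaf", NA, "soil", NA),
    mode = c("sexual", NA, "sexual", "asexual", "asexual"))
  trait_table(c("A_gen1", "B_gen1", "C_gen2", "D_gen1", "E_gen3"),
              cont, cat_df)
}

test_that("log transform maps known values and leaves masked cells missing", {
  tt <- log_transform_traits(make_table())
  expect_equal(tt$continuous["A_gen1", "size"], 1)
  expect_equal(tt$continuous["B_gen1", "size"], 0)
  expect_true(is.na(tt$continuous["D_gen1", "size"]))
  expect_true(all(tt$log_scale))
  # zero shifted by half the smallest positive value (10/2 = 5)
  expect_equal(tt$continuous["E_gen3", "eggs"], log(0 + 5))
  expect_error(log_transform_traits(tt), "already")
})

test_that("negative observed values abort the log transform by name", {
  bad <- trait_table("sp1", cbind(size = -1))
  expect_error(log_transform_traits(bad), "size.*sp1")
})

test_that("categorical backfill fills by genus then family, never touching
          observed cells", {
  tt <- make_table()
  out <- backfill_categorical(tt, toy_taxonomy())
  # E_gen3 (gen3/fam2) has no observed relative for substrate -> unfilled
  expect_true(is.na(out$categorical["E_gen3", "substrate"]))
  expect_match(attr(out$provenance, "unfilled"), "E_gen3:substrate",
               all = FALSE)
  # C_gen2 has no congener; falls back to family mode of fam1 = leaf
  expect_equal(out$categorical["C_gen2", "substrate"], "leaf")
  expect_equal(out$provenance["C_gen2", "substrate"], "family")
  # B_gen1's genus mode for 'mode' is tied sexual/asexual -> lexicographic
  expect_equal(out$categorical["B_gen1", "mode"], "asexual")
  expect_match(attr(out$provenance, "ties"), "B_gen1:mode", all = FALSE)
  # observed cells identical
  obs <- !is.na(tt$categorical)
  expect_identical(out$categorical[obs], tt$categorical[obs])
})

test_that("a genus mode fills a missing congener with genus provenance", {
  cont <- cbind(x = c(1, 2, 3))
  cat_df <- data.frame(sub = c("egg-on-leaf", "egg-on-leaf", NA))
  tt <- trait_table(c("A_gen1", "B_gen1", "D_gen1"), cont, cat_df)
  tax <- toy_taxonomy()
  out <- backfill_categorical(tt, tax)
  expect_equal(out$categorical["D_gen1", "sub"], "egg-on-leaf")
  expect_equal(out$provenance["D_gen1", "sub"], "genus")
})

test_that("missingness fractions match hand counts and aggregate correctly", {
  n <- 129
  cont <- cbind(a = c(rep(NA, 24), rnorm(n - 24)),
                b = rnorm(n),
                c = rep(NA_real_, n))
  tt <- trait_table(sprintf("s%03d", 1:n), cont)
  ms <- missingness_summary(tt)
  expect_equal(round(100 * ms$per_trait[["a"]], 1), 18.6)
  expect_equal(ms$per_trait[["b"]], 0)
  expect_equal(ms$per_trait[["c"]], 1)
  # overall equals the cell-weighted mean of per-trait fractions
  expect_equal(ms$overall, mean(ms$per_trait))
})

test_that("collinearity screen recovers rank identities and VIF structure", {
  set.seed(31)
  n <- 200
  x1 <- rnorm(n)
  X <- cbind(x1 = x1, x2 = exp(x1), x3 = rnorm(n), x4 = rnorm(n))
  sc <- collinearity_screen(X, threshold = 5)
  # strictly monotone pair has Spearman correlation exactly 1
  expect_equal(sc$spearman["x1", "x2"], 1)
  # spearman is invariant to monotone transforms
  X2 <- X; X2[, "x3"] <- qlogis(pnorm(X2[, "x3"]))
  expect_equal(collinearity_screen(X2)$spearman, sc$spearman)
  # near-orthogonal simulated predictors: VIF close to 1
  sc2 <- collinearity_screen(X[, c("x1", "x3", "x4")])
  expect_true(all(sc2$vif < 1.1))
  expect_setequal(sc2$retained, c("x1", "x3", "x4"))
})

test_that("VIF retention respects the threshold and flags constants", {
  set.seed(32)
  n <- 300
  z <- rnorm(n)
  # x2 built to sit just under R2 such that VIF is high
  X <- cbind(a = z, b = z + rnorm(n, 0, 0.1), c = rnorm(n))
  sc <- collinearity_screen(X, threshold = 5)
  expect_true(all(sc$vif[c("a", "b")] > 5))
  expect_identical(sc$retained, "c")
  expect_warning(sc3 <- collinearity_screen(cbind(k = rep(1, 10),
                                                  x = rnorm(10))),
                 "constant")
  expect_true(is.infinite(sc3$vif[["k"]]))
})

test_that("trait tables round-trip through delimited text", {
  tt <- make_table()
  f <- tempfile(fileext = ".tsv")
  write_trait_table(tt, f)
  back <- read_trait_table(f, continuous = c("size", "eggs"),
                           categorical = c("substrate", "mode"))
  expect_equal(back$continuous, tt$continuous)
  expect_equal(back$categorical, tt$categorical)
})
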