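test_that("AR(1) predictor draws have the target correlation structure", {
  X <- gen_ar1_predictors(100000, 2, 0.5, seed = 11)
  expect_equal(cor(X[, 1], X[, 2]), 0.5, tolerance = 0.02)
  # independence limit: rho = 0 gives i.i.d. standard normals
  X0 <- gen_ar1_predictors(10000, 3, 0, seed = 12)
  expect_lt(max(abs(cor(X0)[upper.tri(diag(3))])), 0.05)
  ks <- suppressWarnings(ks.test(as.vector(X0[, 2]), "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("AR(1) draws are seeded and reject invalid rho", {
  a <- gen_ar1_predictors(3, 1000, 0.5, seed = 5)
  b <- gen_ar1_predictors(3, 1000, 0.5, seed = 5)
  expect_identical(a, b)
  expect_error(gen_ar1_predictors(5, 3, 1.0), "rho")
  expect_error(gen_ar1_predictors(5, 3, NaN), "rho")
})

test_that("latent discretization fills exact probability blocks", {
  expect_identical(discretize_latent(c(0.1, 0.5, 0.9), rep(1 / 3, 3)),
                   1:3)
  set.seed(4)
  lat <- rnorm(300)
  y <- discretize_latent(lat, rep(1 / 3, 3))
  expect_identical(tabulate(y, 3), rep(100L, 3))
  # Crohn's-like unequal proportions: exact 42/26/59 at n = 127
  y2 <- discretize_latent(rnorm(127), c(42, 26, 59) / 127)
  expect_identical(tabulate(y2, 3), c(42L, 26L, 59L))
  expect_error(discretize_latent(numeric(0), c(0.5, 0.5)), "empty")
})

test_that("discretization is monotone in the latent score", {
  for (s in 1:20) {
    set.seed(s)
    lat <- rnorm(60)
    probs <- as.vector(rmultinom(1, 57, c(0.3, 0.3, 0.4)) + 1) # >= 1 each
    probs <- probs / sum(probs)
    y <- discretize_latent(lat, probs)
    ord <- order(lat)
    expect_true(all(diff(y[ord]) >= 0))
  }
})

test_that("dense AR(1) scenario matches its stated design", {
  cfg <- sim_config("ar1_dense", n = 300, p = 50, seed = 9)
  d <- gen_scenario(cfg)
  expect_s3_class(d, "labeled_dataset")
  expect_identical(tabulate(d$y, 3), rep(100L, 3))
  beta <- attr(d, "provenance")$beta
  expect_true(all(abs(beta) == 0.7))
  # bit-reproducible under the same config
  expect_identical(d$X, gen_scenario(cfg)$X)
})

test_that("sparse scenario honors signal count and unequal classes", {
  cfg <- sim_config("ar1_sparse", n = 127, p = 40,
                    class_probs = c(42, 26, 59) / 127, seed = 3)
  d <- gen_scenario(cfg)
  expect_identical(tabulate(d$y, 3), c(42L, 26L, 59L))
  beta <- attr(d, "provenance")$beta
  expect_true(all(abs(beta[1:10]) == 0.7))
  expect_true(all(beta[11:40] == 0))
})

test_that("mean-shift scenario has block means 1/3/5 on signal features", {
  cfg <- sim_config("independent_shift", n = 300, p = 1000, seed = 21)
  d <- gen_scenario(cfg)
  expect_equal(mean(d$X[201:300, 1:10]), 5, tolerance = 0.1)
  expect_equal(mean(d$X[1:100, 1:10]), 1, tolerance = 0.1)
  expect_equal(mean(d$X[, 11:1000]), 0, tolerance = 0.05)
  expect_identical(d$y, rep(1:3, each = 100))
  expect_error(sim_config("independent_shift",
                          non_proportional_odds = TRUE),
               "not supported")
})

test_that("non-proportional-odds variant keeps class counts and uses two
           coefficient vectors", {
  cfg <- sim_config("ar1_sparse", n = 127, p = 30,
                    class_probs = c(42, 26, 59) / 127,
                    non_proportional_odds = TRUE, seed = 8)
  d <- gen_scenario(cfg)
  expect_identical(tabulate(d$y, 3), c(42L, 26L, 59L))
  prov <- attr(d, "provenance")
  expect_false(all(prov$beta == prov$beta2))
  expect_true(any(prov$beta == prov$beta2)) # only some signs flipped
})

test_that("train/test split partitions the data at the requested sizes", {
  cfg <- sim_config("ar1_dense", n = 300, p = 5, seed = 2)
  d <- gen_scenario(cfg)
  sp <- split_train_test(d, 0.8, seed = 1)
  expect_identical(nrow(sp$train$X), 240L)
  expect_identical(nrow(sp$test$X), 60L)
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
  expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids), d$sample_ids)
  # reproducible
  sp2 <- split_train_test(d, 0.8, seed = 1)
  expect_identical(sp$train$sample_ids, sp2$train$sample_ids)
  expect_error(split_train_test(d, 1.2), "train_fraction")
})
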