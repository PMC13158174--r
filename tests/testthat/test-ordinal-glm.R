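test_that("backward CR restructuring produces the defined expansion", {
  X <- matrix(rnorm(10), 5, 2)
  d <- restructure_backward_cr(X, c(1, 2, 3, 3, 2))
  # cutpoint 2 has the #{y<=2}=3 rows, cutpoint 3 all 5
  expect_length(d$response, 8)
  expect_identical(sum(d$cutpoint == 2), 3L)
  expect_identical(sum(d$cutpoint == 3), 5L)
  expect_identical(d$response[d$cutpoint == 2], c(0L, 1L, 1L))
  # response is 1 iff the source label equals the cutpoint
  expect_identical(d$response, as.integer(c(1, 2, 3, 3, 2)[d$row_origin]
                                          == d$cutpoint))
  # all-top labels: every row at cutpoint C has response 1
  dtop <- restructure_backward_cr(X, rep(3L, 5), C = 3)
  expect_true(all(dtop$response[dtop$cutpoint == 3] == 1))
  # C = 2 reduces to plain binary logistic rows
  d2 <- restructure_backward_cr(matrix(rnorm(8), 4), c(1, 2, 1, 2))
  expect_length(d2$response, 4)
  expect_identical(d2$response, c(0L, 1L, 0L, 1L))
  expect_error(restructure_backward_cr(X, rep(1L, 5), C = 1), "at least 2")
})

test_that("CR class probabilities follow the product formula", {
  # delta_2 = delta_3 = 0.5 at x = 0 -> (0.25, 0.25, 0.5)
  m <- ordbagg:::new_ordinal_glm("continuation_ratio_backward",
                                 alpha = c(0, 0), beta = 0, "l1_grid",
                                 0, 0, 3L)
  expect_equal(drop(class_probabilities(m, matrix(0, 1, 1))),
               c(0.25, 0.25, 0.5))
  # random parameters: rows sum to 1, entries non-negative
  set.seed(13)
  for (rep in 1:10) {
    C <- sample(2:5, 1)
    mm <- ordbagg:::new_ordinal_glm("continuation_ratio_backward",
                                    alpha = sort(rnorm(C - 1)),
                                    beta = rnorm(3), "l1_grid", 0, 0, C)
    pr <- class_probabilities(mm, matrix(rnorm(18), 6, 3))
    expect_true(all(pr >= 0))
    expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-10)
  }
})

test_that("CL class probabilities are successive logistic differences", {
  m <- ordbagg:::new_ordinal_glm("cumulative_logit", alpha = c(0, 1),
                                 beta = c(0, 0), "l1_grid", 0, 0, 3L)
  pr <- class_probabilities(m, matrix(rnorm(10), 5, 2))
  expect_equal(pr, matrix(rep(c(0.5, plogis(1) - 0.5, 1 - plogis(1)),
                              each = 5), 5, 3), tolerance = 1e-12)
  # argmax of (0.5, 0.231, 0.269) is class 1 everywhere
  expect_identical(predict_class(m, matrix(rnorm(10), 5, 2)), rep(1L, 5))
  # cumulative probabilities are monotone in c for random models
  set.seed(17)
  for (rep in 1:10) {
    C <- sample(3:5, 1)
    mm <- ordbagg:::new_ordinal_glm("cumulative_logit",
                                    alpha = sort(rnorm(C - 1)),
                                    beta = rnorm(2), "l1_grid", 0, 0, C)
    pr <- class_probabilities(mm, matrix(rnorm(8), 4, 2))
    expect_true(all(pr >= 0))
    expect_equal(rowSums(pr), rep(1, 4), tolerance = 1e-10)
    cum <- t(apply(pr, 1, cumsum))
    expect_true(all(diff(t(cum)) >= -1e-12))
  }
})

test_that("argmax prediction breaks ties toward the lower class", {
  # build degenerate CR model with delta_2 = delta_3 = 2/3 at x = 0:
  # P = (1/9, 2/9, 2/3); instead test the tie rule directly on max.col
  probs <- matrix(c(0.4, 0.4, 0.2), 1)
  expect_identical(max.col(probs, ties.method = "first"), 1L)
  # and end to end through a fitted constant model
  m <- ordbagg:::new_ordinal_glm("cumulative_logit", alpha = c(0, 20),
                                 beta = 0, "l1_grid", 0, 0, 3L)
  expect_identical(predict_class(m, matrix(0, 2, 1)), c(1L, 1L))
})

test_that("unpenalized CR fit agrees with direct likelihood maximization", {
  td <- toy_ordinal_data(n = 40, p = 1, C = 3, seed = 6)
  oracle <- fit_cr_direct(td$X, td$y)
  fit <- fit_cr_l1(td$X, td$y, lambda = c(0.001, 0))
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-3)
  expect_equal(fit$alpha, oracle$alpha, tolerance = 5e-3)
  # expanded-data loglik at the solution matches the direct formulation
  d <- restructure_backward_cr(td$X, td$y)
  expect_equal(fit$loglik,
               cr_direct_loglik(c(fit$alpha, fit$beta), td$X, td$y, 3),
               tolerance = 1e-6)
})

test_that("unpenalized CL fit matches both a direct optimizer and polr", {
  td <- toy_ordinal_data(n = 60, p = 1, C = 3, seed = 7)
  fit <- fit_cl_l1(td$X, td$y, lambda = 0, tol = 1e-12, max_iter = 20000)
  oracle <- fit_cl_direct(td$X, td$y)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-3)
  expect_equal(fit$alpha, oracle$alpha, tolerance = 1e-3)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  # MASS::polr parameterizes logit P(Y<=c) = zeta_c - beta x
  pol <- MASS::polr(factor(td$y) ~ td$X, method = "logistic")
  expect_equal(fit$beta, -unname(coef(pol)), tolerance = 1e-3)
  expect_equal(fit$alpha, unname(pol$zeta), tolerance = 1e-3)
})

test_that("lambda at or above lambda_max yields the null model", {
  td <- toy_ordinal_data(n = 60, p = 8, C = 3, seed = 9)
  big <- 1e6
  f1 <- fit_cr_l1(td$X, td$y, lambda = big)
  expect_true(all(f1$beta == 0))
  f2 <- fit_cl_l1(td$X, td$y, lambda = big)
  expect_true(all(abs(f2$beta) < 1e-10))
  # null CL model predicts the marginal class frequencies
  pr <- class_probabilities(f2, td$X[1:3, , drop = FALSE])
  marg <- tabulate(td$y, 3) / length(td$y)
  expect_equal(pr[1, ], marg, tolerance = 1e-3)
})

test_that("path-wise CR fit enters variables by score and tracks the grid
           fit", {
  td <- toy_ordinal_data(n = 80, p = 12, C = 3, seed = 10)
  fit <- fit_cr_l1_path(td$X, td$y)
  # first entrant is the largest null-model score component
  d <- restructure_backward_cr(scale(td$X), td$y)
  D <- ordbagg:::cr_design_matrix(d)
  th0 <- numeric(ncol(D))
  for (j in 2:3) {
    rj <- d$response[d$cutpoint == j]
    th0[j - 1] <- qlogis(mean(rj))
  }
  g <- crossprod(D, d$response - plogis(drop(D %*% th0)))
  expect_identical(fit$first_entry, which.max(abs(g[-(1:2)])))
  # lambda path strictly decreasing
  expect_true(all(diff(fit$lambda_path) < 0))
})

test_that("grid and path CR fits give near-identical predictions on
           strong-signal data", {
  cfg <- sim_config("independent_shift", n = 150, p = 40, seed = 31)
  d <- gen_scenario(cfg)
  sp <- split_train_test(d, 0.8, seed = 1)
  f_grid <- fit_cr_l1(sp$train$X, sp$train$y)
  f_path <- fit_cr_l1_path(sp$train$X, sp$train$y)
  agree <- mean(predict_class(f_grid, sp$test$X) ==
                  predict_class(f_path, sp$test$X))
  expect_gte(agree, 0.9)
  expect_gte(accuracy(sp$train$y, predict_class(f_grid, sp$train$X)), 0.8)
})

test_that("GMIFS increments satisfy the L1 budget and pick the
           steepest-gradient coordinate first", {
  td <- toy_ordinal_data(n = 50, p = 6, C = 3, seed = 12)
  one <- fit_cl_gmifs(td$X, td$y, max_steps = 1, patience = 5)
  # exactly one coordinate moved, by epsilon, in the score direction
  moved <- which(one$beta != 0)
  score <- cl_numeric_score(scale(td$X), td$y)
  if (length(moved) == 1L) {
    expect_identical(moved, which.max(abs(score)))
    expect_equal(abs(one$beta[moved] * sd(td$X[, moved])), 0.001,
                 tolerance = 1e-9)
  } else {
    expect_identical(moved, integer(0)) # step 0 (null) had the best AIC
  }
  many <- fit_cl_gmifs(td$X, td$y, max_steps = 400, patience = 400)
  s <- many$lambda_or_steps
  beta_std <- many$beta * apply(td$X, 2, sd)
  expect_lte(sum(abs(beta_std)), s * 0.001 + 1e-9)
})

test_that("GMIFS and grid CL fits land close on strong-signal data", {
  cfg <- sim_config("independent_shift", n = 150, p = 40, seed = 33)
  d <- gen_scenario(cfg)
  sp <- split_train_test(d, 0.8, seed = 2)
  f_l1 <- fit_cl_l1(sp$train$X, sp$train$y)
  f_gm <- fit_cl_gmifs(sp$train$X, sp$train$y, max_steps = 4000)
  a1 <- accuracy(sp$test$y, predict_class(f_l1, sp$test$X))
  a2 <- accuracy(sp$test$y, predict_class(f_gm, sp$test$X))
  expect_lte(abs(a1 - a2), 0.1)
})

test_that("selected AIC is invariant to training sample order", {
  td <- toy_ordinal_data(n = 60, p = 10, C = 3, seed = 14)
  perm <- sample(60)
  f1 <- fit_cl_l1(td$X, td$y)
  f2 <- fit_cl_l1(td$X[perm, , drop = FALSE], td$y[perm])
  expect_equal(f1$aic, f2$aic, tolerance = 1e-6)
  g1 <- fit_cr_l1(td$X, td$y)
  g2 <- fit_cr_l1(td$X[perm, , drop = FALSE], td$y[perm])
  expect_equal(g1$aic, g2$aic, tolerance = 1e-6)
})

test_that("ordinal models survive a JSON round trip", {
  td <- toy_ordinal_data(n = 50, p = 5, C = 3, seed = 15)
  fit <- fit_cl_l1(td$X, td$y)
  js <- ordinal_glm_to_json(fit)
  back <- ordinal_glm_from_json(js)
  expect_equal(back$alpha, fit$alpha)
  expect_equal(back$beta, fit$beta)
  expect_identical(predict_class(back, td$X), predict_class(fit, td$X))
})
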