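test_that("soft_threshold implements the L1 proximal operator", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  z <- c(-2, -0.3, 0, 0.3, 2)
  expect_equal(soft_threshold(z, 0), z)
  expect_equal(soft_threshold(z, 0.5), c(-1.5, 0, 0, 0, 1.5))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("penalty_spec validates its invariants", {
  expect_error(penalty_spec(alpha = 2), "alpha")
  expect_error(penalty_spec(alpha = 0), "explicit")
  expect_s3_class(penalty_spec(alpha = 0, lambda = c(3, 2, 1)),
                  "penalty_spec")
  expect_error(penalty_spec(lambda = c(1, 2)), "decreasing")
  expect_error(penalty_spec(criterion = "bogus"), "criterion|arg")
})

test_that("the path starts empty at lambda_max", {
  fx <- make_fixture(n = 100, m = 50, seed = 61)
  p <- en_fit_path(fx$Z, fx$adj$y_star, penalty_spec(alpha = 1,
                                                     n_lambda = 20))
  expect_equal(p$df[1], 0L)
  expect_gt(p$df[20], 0L)
  expect_true(all(p$converged))
})

test_that("the single-predictor update matches the closed form", {
  # standardized z with z'y/n = 2, lambda = 1, alpha = 0.5:
  # coefficient = S(2, 0.5) / (1 + 0.5) = 1
  set.seed(60)
  n <- 50
  z <- std_cols(matrix(rnorm(n), ncol = 1))
  y <- 2 * drop(z)
  p <- en_fit_path(matrix(z, ncol = 1), y,
                   penalty_spec(alpha = 0.5, lambda = c(1)))
  expect_equal(unname(p$beta[1, 1]), 1, tolerance = 1e-6)
})

test_that("lasso solutions satisfy KKT and match exhaustive enumeration", {
  set.seed(62)
  n <- 40
  X <- std_cols(matrix(rnorm(n * 5), n, 5))
  b_true <- c(2, -1, 0, 0, 0.5)
  y <- drop(X %*% b_true) + rnorm(n, sd = 0.5)
  y <- y - mean(y)
  for (lam in c(0.8, 0.3, 0.05)) {
    p <- en_fit_path(X, y, penalty_spec(alpha = 1, lambda = c(lam),
                                        standardize = FALSE))
    b_hat <- p$beta[, 1]
    expect_lt(enet_kkt_violation(X, y, b_hat, lam, 1), 1e-6)
    b_oracle <- enumerate_enet(X, y, lam, 1)
    expect_equal(unname(b_hat), b_oracle, tolerance = 1e-6)
  }
  # mixed penalty against the same oracle
  p <- en_fit_path(X, y, penalty_spec(alpha = 0.4, lambda = c(0.3),
                                      standardize = FALSE))
  expect_equal(unname(p$beta[, 1]), enumerate_enet(X, y, 0.3, 0.4),
               tolerance = 1e-6)
})

test_that("the objective never increases within a sweep", {
  fx <- make_fixture(n = 150, m = 200, seed = 63)
  for (a in c(1, 0.5, 0.001)) {
    spec <- if (a == 0.001) {
      penalty_spec(alpha = a, n_lambda = 30, lambda_min_ratio = 1e-4)
    } else {
      penalty_spec(alpha = a, n_lambda = 30)
    }
    p <- en_fit_path(fx$Z, fx$adj$y_star, spec)
    expect_lt(max(p$obj_increase), 1e-8 * var(fx$adj$y_star))
  }
})

test_that("near-ridge solutions are continuous in alpha", {
  fx <- make_fixture(n = 120, m = 60, seed = 64)
  y <- fx$adj$y_star
  # same explicit grid for both alphas
  lam <- exp(seq(log(50), log(0.05), length.out = 25))
  p3 <- en_fit_path(fx$Z, y, penalty_spec(alpha = 1e-3, lambda = lam))
  p4 <- en_fit_path(fx$Z, y, penalty_spec(alpha = 1e-4, lambda = lam))
  pred3 <- predict(p3, fx$Z, s = "all")
  pred4 <- predict(p4, fx$Z, s = "all")
  # prediction difference per lambda, as a fraction of the response scale
  # (the prediction norm itself vanishes at the top of the path)
  rel <- sqrt(colMeans((pred3 - pred4)^2)) / sd(y)
  expect_lt(max(rel), 0.01)
})

test_that("glmnet agrees with the coordinate-descent solver", {
  # glmnet standardizes y internally, which rescales the ridge part of its
  # penalty by 1/s with s = sqrt(mean((y - ybar)^2)); its (lambda, alpha)
  # maps onto this package's parameterization via
  #   L1 weight lam*a, L2 weight lam*(1-a)/s.
  fx <- make_fixture(n = 100, m = 40, seed = 65)
  X <- unclass(fx$Z)
  y <- unname(fx$adj$y_star)
  s <- sqrt(mean((y - mean(y))^2))
  for (a in c(1, 0.5)) {
    gn <- glmnet::glmnet(X, y, alpha = a, thresh = 1e-12,
                         standardize = TRUE)
    lam <- gn$lambda[c(5, 15, 30)]
    l1 <- lam * a
    l2 <- lam * (1 - a) / s
    lam_eq <- l1 + l2
    for (i in seq_along(lam)) {
      p <- en_fit_path(X, y, penalty_spec(alpha = l1[i] / lam_eq[i],
                                          lambda = lam_eq[i]))
      ref <- as.numeric(coef(gn, s = lam[i], exact = TRUE, x = X, y = y))
      got <- c(p$a0[1], p$beta[, 1])
      expect_equal(got, ref, tolerance = 1e-4)
    }
  }
})

test_that("cross-validated selection behaves on signal and noise", {
  # planted-QTL trait: the chosen model must beat the empty model
  st <- simulate_study(300, 500, trait_architecture("sparse", h2 = 0.5,
                                                    pi_null = 0.98),
                       seed = 66)
  adj <- adjust_phenotype(st$phenotypes)
  Z <- impute_missing(st$genotypes)
  sel <- en_cv_select(Z, adj$y_star, penalty_spec(alpha = 1, n_lambda = 40,
                                                  seed = 2))
  expect_lt(sel$cv_mse[sel$index_chosen], sel$cv_mse[1])
  expect_gt(sel$df[sel$index_chosen], 0)
  # the 1SE rule never picks a smaller lambda than minMSE
  expect_lte(sel$index_1se, sel$index_min)
  sel1 <- en_cv_select(Z, adj$y_star,
                       penalty_spec(alpha = 1, n_lambda = 40, seed = 2,
                                    criterion = "minMSE_1SE"))
  expect_gte(sel1$lambda_chosen, sel$lambda_chosen)
  expect_equal(sel1$cv_mse, sel$cv_mse) # same folds, same grid
})

test_that("degenerate internal folds are skipped with a warning", {
  Z <- simulate_genotypes(20, 10, seed = 67)
  y <- c(rep(0, 4), rnorm(16))
  plan_spec <- penalty_spec(alpha = 1, n_lambda = 10, cv_folds = 5,
                            seed = 1)
  # constant y altogether -> no grid
  expect_error(en_fit_path(impute_missing(Z), rep(1, 20), plan_spec),
               "constant")
})
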