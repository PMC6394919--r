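test_that("kfold_split yields near-equal, seed-stable folds", {
  plan <- kfold_split(seq_len(1217), k = 5, seed = 3)
  sizes <- sort(as.integer(table(plan$folds)), decreasing = TRUE)
  expect_equal(sizes, c(244L, 244L, 243L, 243L, 243L))
  expect_equal(sum(table(plan$folds)), 1217L)

  plan10 <- kfold_split(seq_len(10), k = 5, seed = 1)
  expect_true(all(table(plan10$folds) == 2L))

  expect_identical(kfold_split(letters, 4, seed = 11)$folds,
                   kfold_split(letters, 4, seed = 11)$folds)
  expect_false(identical(kfold_split(letters, 4, seed = 11)$folds,
                         kfold_split(letters, 4, seed = 12)$folds))
  expect_error(kfold_split(1:4, k = 5), "cannot split")
})

test_that("generation_split cuts strictly at the cutoff year", {
  years <- setNames(c(rep(2008:2013, each = 3), 2014, 2014),
                    paste0("a", 1:20))
  plan <- generation_split(years, 2013)
  expect_equal(sum(plan$train), 18L)
  expect_equal(sum(plan$test), 2L)
  expect_error(generation_split(rep(2010, 5), 2013), "empty test")
  expect_error(generation_split(c(a = NA, b = 2010), 2009), "birth year")
  # a cohort with year counts proportional to a 1135:82 design
  counts <- c(189, 189, 189, 189, 189, 190, 82)
  big <- rep(2008:2014, counts)
  pb <- generation_split(big, 2013)
  expect_equal(sum(pb$train), 1135L)
  expect_equal(sum(pb$test), 82L)
})

test_that("accuracy is the Pearson correlation with strict preconditions", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(accuracy(c(1, 2, 3), c(-1, -2, -3)), -1)
  # hand arithmetic: cov = 1.5, var = 1 and 7/3 -> r = 1.5/sqrt(7/3)
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-6)
  expect_error(accuracy(c(1, 2), c(3, 4)), "at least 3")
  expect_error(accuracy(c(1, 1, 1), c(1, 2, 3)), "constant")
  # symmetry and invariance to positive affine rescaling
  set.seed(70)
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(accuracy(a, b), accuracy(b, a))
  expect_equal(accuracy(a, 3 * b + 7), accuracy(a, b))
})

test_that("realized accuracy rescales by sqrt heritability", {
  expect_equal(realized_accuracy(0.5, 0.25), 1)
  expect_equal(realized_accuracy(0.25, 0.44), 0.25 / sqrt(0.44))
  expect_lt(abs(realized_accuracy(0.25, 0.44) - 0.3769), 1e-4)
  expect_equal(realized_accuracy(0, 0.3), 0)
  expect_error(realized_accuracy(0.5, 0), "h2")
  expect_warning(realized_accuracy(0.9, 0.25), "exceeds 1")
})

test_that("run_comparison scores all methods on identical folds", {
  st <- simulate_study(150, 120, trait_architecture("polygenic", h2 = 0.6),
                       seed = 71)
  adj <- adjust_phenotype(st$phenotypes)
  plan <- kfold_split(names(adj$y_star), k = 3, seed = 5)
  rep_ <- run_comparison(
    st$genotypes, adj$y_star,
    methods = list(gblup = list(method = "gblup"),
                   en = list(method = "en", alpha = 0.001, n_lambda = 20,
                             lambda_min_ratio = 1e-4)),
    plan = plan, seed = 6
  )
  expect_s3_class(rep_, "accuracy_report")
  expect_equal(dim(rep_$fold_r), c(3L, 2L))
  expect_true(all(is.finite(rep_$fold_r)))
  expect_equal(rep_$summary$mean_r, unname(colMeans(rep_$fold_r)))
  # realized accuracy uses the single whole-data h2, exactly
  expect_equal(rep_$summary$realized,
               rep_$summary$mean_r / sqrt(rep_$h2))
  # every individual got exactly one out-of-fold prediction per method
  expect_true(all(!is.na(rep_$predictions)))
  # the fold checksum is reproducible for the same plan
  rep2 <- run_comparison(st$genotypes, adj$y_star,
                         methods = list(gblup = list(method = "gblup")),
                         plan = plan, seed = 6)
  expect_equal(rep2$fold_checksum, rep_$fold_checksum)
})

test_that("a failing method yields NA cells without stopping the run", {
  st <- simulate_study(60, 40, seed = 72)
  adj <- adjust_phenotype(st$phenotypes)
  plan <- kfold_split(names(adj$y_star), k = 3, seed = 2)
  w <- capture_warnings(
    rep_ <- run_comparison(
      st$genotypes, adj$y_star,
      methods = list(gblup = list(method = "gblup"),
                     broken = list(method = "nope")),
      plan = plan, seed = 3
    )
  )
  expect_true(any(grepl("failed on fold", w)))
  expect_true(all(is.na(rep_$fold_r[, "broken"])))
  expect_true(all(is.finite(rep_$fold_r[, "gblup"])))
  expect_equal(rep_$summary$n_folds, c(3L, 0L))
})

test_that("accuracy grows with training size on simulated data", {
  mean_acc <- function(n) {
    acc <- vapply(1:8, function(r) {
      st <- simulate_study(n, 150, trait_architecture("polygenic", h2 = 0.5),
                           seed = 4000 + 17 * r)
      adj <- adjust_phenotype(st$phenotypes)
      plan <- kfold_split(names(adj$y_star), k = 5, seed = 5000 + r)
      rep_ <- run_comparison(st$genotypes, adj$y_star,
                             methods = list(gblup = list(method = "gblup")),
                             plan = plan, seed = 6000 + r)
      rep_$summary$mean_r
    }, numeric(1))
    mean(acc)
  }
  expect_gt(mean_acc(600), mean_acc(200))
})
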