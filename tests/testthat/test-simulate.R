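test_that("simulated genotypes follow HWE coding and are seed-deterministic", {
  g <- simulate_genotypes(4, 3, maf_range = c(0.5, 0.5), missing_rate = 0,
                          seed = 1)
  expect_equal(dim(g), c(4L, 3L))
  expect_true(all(unclass(g) %in% c(-1, 0, 1)))

  # at MAF 0.5 the long-run heterozygote fraction is 0.5
  big <- simulate_genotypes(4000, 20, maf_range = c(0.5, 0.5), seed = 2)
  het <- mean(unclass(big) == 0)
  expect_lt(abs(het - 0.5), 0.01)

  expect_identical(simulate_genotypes(50, 40, seed = 7),
                   simulate_genotypes(50, 40, seed = 7))
  expect_false(identical(unclass(simulate_genotypes(50, 40, seed = 7)),
                         unclass(simulate_genotypes(50, 40, seed = 8))))
})

test_that("missingness is placed at the requested rate", {
  g <- simulate_genotypes(1000, 200, maf_range = c(0.05, 0.5),
                          missing_rate = 0.02, seed = 7)
  expect_lt(abs(mean(is.na(g)) - 0.02), 0.01)
})

test_that("invalid generator parameters error", {
  expect_error(simulate_genotypes(4, 3, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(simulate_genotypes(4, 3, maf_range = c(0.1, 0.6)),
               "maf_range")
  expect_error(simulate_genotypes(4, 3, maf_range = c(0.4, 0.2)),
               "maf_range")
  expect_error(simulate_genotypes(1, 3), "n")
  expect_error(simulate_genotypes(4, 3, missing_rate = 1), "missing_rate")
})

test_that("sparse architectures zero exactly round(pi_null * m) effects", {
  arch <- trait_architecture("sparse", pi_null = 0.9)
  eff <- simulate_effects(10, arch, seed = 3)
  expect_identical(sum(eff$gamma != 0), 1L)
  # rescaling keeps total squared effect at the polygenic expectation
  expect_equal(sum(eff$gamma^2), 10 * arch$effect_scale)

  expect_error(simulate_effects(10, trait_architecture("sparse",
                                                       pi_null = 0.99)),
               "no nonzero")
})

test_that("polygenic effects are dense draws from a zero-mean normal", {
  eff <- simulate_effects(1000, trait_architecture("polygenic"), seed = 5)
  expect_identical(sum(eff$gamma == 0), 0L)
  expect_lt(abs(mean(eff$gamma)), 3 / sqrt(1000))
})

test_that("architecture invariants are enforced", {
  expect_error(trait_architecture("polygenic", pi_null = 0.5), "pi_null")
  expect_error(trait_architecture("sparse", pi_null = 1), "pi_null")
  expect_error(trait_architecture("sparse", h2 = 1.2), "h2")
})

test_that("phenotypes decompose exactly into Xb + g + e at the target h2", {
  st <- simulate_study(2000, 1000, trait_architecture("polygenic", h2 = 0.5),
                       seed = 11)
  with(st, {
    expect_equal(phenotypes$y,
                 components$xb + unname(true_breeding_values) + components$e)
  })
  # realized h2 from stored components
  expect_lt(abs(realized_h2(st) - 0.5), 0.05)
  # subtracting the known fixed part reproduces corr(g, g + e) exactly
  resid_oracle <- st$phenotypes$y - st$components$xb
  expect_equal(cor(resid_oracle, unname(st$true_breeding_values)),
               cor(unname(st$true_breeding_values) + st$components$e,
                   unname(st$true_breeding_values)))
  # breeding values equal the imputed genotype-effect product
  Z <- impute_missing(st$genotypes)
  expect_equal(unname(gebv_from_effects(Z, st$true_effects)),
               unname(st$true_breeding_values))
})

test_that("the null trait (h2 = 0) is pure fixed effects plus noise", {
  arch <- trait_architecture("polygenic", h2 = 0)
  g <- simulate_genotypes(100, 50, seed = 1)
  eff <- simulate_effects(50, arch, seed = 2)
  expect_true(all(eff$gamma == 0))
  st <- simulate_phenotypes(g, eff, arch, seed = 3)
  expect_equal(st$phenotypes$y, st$components$xb + st$components$e)
  expect_true(all(st$true_breeding_values == 0))
  # h2 = 0 with genuinely nonzero effects is rejected
  eff2 <- marker_effects(0, rep(1, 50))
  expect_error(simulate_phenotypes(g, eff2, arch, seed = 3), "h2 = 0")
})

test_that("degenerate architectures are rejected", {
  g <- genotype_matrix(matrix(0, 10, 4)) # all heterozygotes
  eff <- marker_effects(0, rep(1, 4))
  arch <- trait_architecture("polygenic", h2 = 0.5)
  expect_error(simulate_phenotypes(g, eff, arch), "degenerate")
})

test_that("heritability is calibrated over replicates", {
  h2 <- vapply(1:20, function(s) {
    realized_h2(simulate_study(1000, 500,
                               trait_architecture("polygenic", h2 = 0.5),
                               seed = 100 + s))
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 0.03)
})

test_that("simulated markers pass the HWE filter at the stated rate", {
  g <- simulate_genotypes(500, 2000, maf_range = c(0.05, 0.5), seed = 9)
  st <- genopred:::marker_qc_stats(g)
  expect_gte(mean(st$hwe_p > 1e-5), 0.99)
})

test_that("study-level determinism holds end to end", {
  a <- simulate_study(80, 60, trait_architecture("sparse", pi_null = 0.5),
                      missing_rate = 0.03, seed = 21)
  b <- simulate_study(80, 60, trait_architecture("sparse", pi_null = 0.5),
                      missing_rate = 0.03, seed = 21)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(a$true_effects, b$true_effects)
})
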