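# Build a genotype matrix column-by-column from genotype counts.
geno_from_counts <- function(...) {
  cols <- list(...)
  n <- length(cols[[1L]])
  genotype_matrix(do.call(cbind, cols))
}

test_that("hwe_pvalue matches the 1-df chi-square oracle", {
  expect_equal(hwe_pvalue(25, 50, 25), 1) # chi-square 0
  expect_equal(hwe_pvalue(100, 0, 0), 1)  # monomorphic convention
  expect_equal(hwe_pvalue(0, 0, 57), 1)
  # (30,40,30): expected (25,50,25), chi-square = 1 + 2 + 1 = 4
  expect_equal(hwe_pvalue(30, 40, 30), pchisq(4, 1, lower.tail = FALSE))
  expect_lt(abs(hwe_pvalue(30, 40, 30) - 0.0455), 1e-4)
  # (50,0,50): chi-square 100, far below any floor
  expect_lt(hwe_pvalue(50, 0, 50), 1e-5)
  expect_error(hwe_pvalue(-1, 2, 3), "nonnegative")
  # vectorized
  expect_equal(hwe_pvalue(c(25, 30), c(50, 40), c(25, 30)),
               c(1, pchisq(4, 1, lower.tail = FALSE)))
})

test_that("filter_markers applies strict thresholds and reports reasons", {
  perfect <- rep(c(1, 0, -1), c(25, 50, 25))      # kept
  hwe_bad <- rep(c(1, -1), c(50, 50))             # chi-square 100
  maf_edge <- rep(c(0, -1), c(10, 90))            # MAF exactly 0.05
  low_cr <- c(rep(NA, 6), rep(c(1, 0, -1), c(24, 46, 24))) # CR 0.94
  g <- geno_from_counts(perfect, hwe_bad, maf_edge, low_cr)
  out <- filter_markers(g)
  rep_ <- out$report
  expect_equal(nrow(rep_), 4L)
  expect_equal(rep_$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(rep_$reason, c("", "hwe_fail", "low_maf", "low_call_rate"))
  expect_equal(rep_$maf[3], 0.05)
  expect_equal(rep_$call_rate[4], 0.94)
  expect_identical(colnames(out$genotypes), rep_$marker[1])
  # boundary: call rate exactly at the threshold fails the strict test
  cr_edge <- c(rep(NA, 5), rep(c(1, 0, -1), c(24, 47, 24)))
  out2 <- filter_markers(geno_from_counts(perfect, cr_edge))
  expect_false(out2$report$pass[2])
})

test_that("an all-failing panel raises the empty-panel error", {
  g <- geno_from_counts(rep(c(1, -1), c(50, 50)))
  expect_error(filter_markers(g), "all markers removed")
})

test_that("filter_samples removes > 10% missing individuals, strictly", {
  vals <- matrix(rep(c(1, 0, -1), length.out = 300), 3, 100)
  vals[1, 1:11] <- NA # 11% missing -> removed
  vals[2, 1:10] <- NA # exactly 10% -> kept
  g <- genotype_matrix(vals)
  out <- filter_samples(g)
  expect_identical(rownames(out), rownames(g)[2:3])
  # fully observed matrix is untouched
  g2 <- simulate_genotypes(10, 20, seed = 1)
  expect_identical(unclass(filter_samples(g2)), unclass(g2))
})

test_that("impute_missing fills marker means and only those", {
  g <- genotype_matrix(cbind(c(1, -1, NA), c(1, 1, NA), c(0, 1, -1)))
  out <- impute_missing(g)
  expect_equal(unname(unclass(out)[3, ]), c(0, 1, -1))
  expect_equal(unclass(out)[1:2, ], unclass(g)[1:2, ])
  expect_true(isTRUE(attr(out, "imputed")))
  # complete matrix unchanged
  gc <- simulate_genotypes(10, 5, seed = 2)
  expect_equal(unclass(impute_missing(gc)), unclass(gc),
               ignore_attr = TRUE)
  # fully missing marker points at filter_markers
  gbad <- genotype_matrix(cbind(c(1, -1, 0), c(NA, NA, NA)))
  expect_error(impute_missing(gbad), "filter_markers")
})

test_that("the QC pipeline is idempotent on its own output", {
  g <- simulate_genotypes(150, 300, maf_range = c(0.05, 0.5),
                          missing_rate = 0.02, seed = 13)
  pass1 <- run_qc(g, impute = FALSE)
  pass2 <- run_qc(pass1$genotypes, impute = FALSE)
  expect_identical(dim(pass2$genotypes), dim(pass1$genotypes))
  expect_identical(unclass(pass2$genotypes), unclass(pass1$genotypes))
  expect_true(all(pass2$marker_report$pass))
  # report bookkeeping: rows = input markers; kept + removed = total
  expect_equal(nrow(pass1$marker_report), 300L)
  expect_equal(sum(pass1$marker_report$pass) +
                 sum(!pass1$marker_report$pass), 300L)
})
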