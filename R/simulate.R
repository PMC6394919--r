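#' Describe an additive trait architecture
#'
#' A trait architecture states how many markers carry effects and how much
#' of the phenotypic variance is additive-genetic. Two kinds are supported:
#' `"polygenic"` (every marker has a normal effect, the infinitesimal model)
#' and `"sparse"` (a proportion `pi_null` of markers has exactly zero
#' effect, mirroring the spike-and-slab assumption of BayesB).
#'
#' @param kind `"polygenic"` or `"sparse"`.
#' @param h2 target narrow-sense heritability in `[0, 1]`. `h2 = 0` is the
#'   explicit null trait (all effects zero, phenotype is fixed effects plus
#'   noise); `h2 = 1` means no residual noise.
#' @param pi_null proportion of markers with exactly zero effect, in
#'   `[0, 1)`. Must be 0 for `kind = "polygenic"`.
#' @param effect_scale variance of nonzero marker effects before the
#'   heritability rescaling applied at phenotype simulation.
#' @return a `trait_architecture` list.
#' @examples
#' trait_architecture("sparse", h2 = 0.5, pi_null = 0.99)
#' @export
trait_architecture <- function(kind = c("polygenic", "sparse"), h2 = 0.5,
                               pi_null = if (kind == "sparse") 0.9 else 0,
                               effect_scale = 1) {
  kind <- match.arg(kind)
  check_scalar(h2, "h2", 0, 1)
  check_scalar(pi_null, "pi_null", 0, 1, strict_upper = TRUE)
  check_scalar(effect_scale, "effect_scale", 0, strict_lower = TRUE)
  if (kind == "polygenic" && pi_null != 0) {
    stop("a polygenic architecture requires pi_null = 0", call. = FALSE)
  }
  structure(list(kind = kind, h2 = h2, pi_null = pi_null,
                 effect_scale = effect_scale),
            class = "trait_architecture")
}

#' Describe the fixed effects of the simulated phenotype model
#'
#' The simulated phenotype follows `y = Xb + g + e` where `Xb` collects a
#' sex effect, a birth-year contemporary-group effect, and two continuous
#' covariates (fattening duration in days and initial body weight in kg)
#' with global slopes. Default magnitudes are on the scale of a carcass
#' weight-like trait (phenotypic SD of a few tens of kg).
#'
#' @param sex_levels,sex_coefs factor levels and additive level effects.
#' @param year_levels,year_coefs birth-year levels and level effects (a mild
#'   environmental trend by default).
#' @param year_weights sampling weights over `year_levels` (uniform by
#'   default); lets a cohort emulate unbalanced year classes.
#' @param covariates named list; each element has `mean`, `sd` and `slope`.
#' @return a `fixed_effects_spec` list.
#' @export
fixed_effects_spec <- function(
    sex_levels = c("M", "F"),
    sex_coefs = c(M = 0, F = -20),
    year_levels = 2008:2014,
    year_coefs = setNames(seq(0, 12, length.out = length(year_levels)),
                          year_levels),
    year_weights = NULL,
    covariates = list(
      fatten_days = list(mean = 300, sd = 25, slope = 0.05),
      init_weight = list(mean = 250, sd = 30, slope = 0.4)
    )) {
  if (length(sex_levels) != length(sex_coefs)) {
    stop("`sex_coefs` must have one value per sex level", call. = FALSE)
  }
  if (length(year_levels) != length(year_coefs)) {
    stop("`year_coefs` must have one value per year level", call. = FALSE)
  }
  if (!is.null(year_weights) && length(year_weights) != length(year_levels)) {
    stop("`year_weights` must have one value per year level", call. = FALSE)
  }
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (!all(c("mean", "sd", "slope") %in% names(cv))) {
      stop(sprintf("covariate `%s` needs mean, sd and slope", nm),
           call. = FALSE)
    }
  }
  structure(list(sex_levels = as.character(sex_levels),
                 sex_coefs = setNames(as.numeric(sex_coefs), sex_levels),
                 year_levels = as.integer(year_levels),
                 year_coefs = setNames(as.numeric(year_coefs), year_levels),
                 year_weights = year_weights,
                 covariates = covariates),
            class = "fixed_effects_spec")
}

#' Simulate diploid SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Each marker draws a minor-allele frequency uniformly from `maf_range`,
#' then genotypes are sampled as binomial(2, MAF) allele dosages, coded
#' `dosage - 1` so that `1/0/-1` correspond to the genotypes `11/12/22`.
#' Markers are in linkage equilibrium. Missing calls are placed
#' independently at `missing_rate`.
#'
#' @param n number of individuals (>= 2).
#' @param m number of markers (>= 1).
#' @param maf_range length-2 interval within `(0, 0.5]`.
#' @param missing_rate per-entry missingness proportion in `[0, 1)`.
#' @param seed RNG seed; identical seeds give bit-identical matrices.
#' @return a [genotype_matrix()].
#' @examples
#' g <- simulate_genotypes(10, 5, seed = 1)
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = 1L) {
  n <- check_count(n, "n", 2L)
  m <- check_count(m, "m", 1L)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      any(!is.finite(maf_range)) || maf_range[1L] > maf_range[2L] ||
      maf_range[1L] <= 0 || maf_range[2L] > 0.5) {
    stop("`maf_range` must be an interval within (0, 0.5]", call. = FALSE)
  }
  check_scalar(missing_rate, "missing_rate", 0, 1, strict_upper = TRUE)
  with_seed(seed, {
    maf <- runif(m, maf_range[1L], maf_range[2L])
    g <- matrix(rbinom(n * m, 2L, rep(maf, each = n)) - 1, n, m)
    if (missing_rate > 0) {
      g[runif(n * m) < missing_rate] <- NA_real_
    }
    new_genotype_matrix(g)
  })
}

#' Simulate additive marker effects
#'
#' Polygenic architectures draw all `m` effects from `N(0, effect_scale)`.
#' Sparse architectures zero out `round(pi_null * m)` randomly chosen
#' markers and rescale the remaining effects so the total sum of squared
#' effects matches the polygenic expectation `m * effect_scale`, making the
#' generated genetic variance comparable across architectures.
#'
#' @param m marker count.
#' @param architecture a [trait_architecture()].
#' @param seed RNG seed.
#' @return a [marker_effects()] with `mu = 0`.
#' @export
simulate_effects <- function(m, architecture, seed = 1L) {
  m <- check_count(m, "m", 1L)
  stopifnot(inherits(architecture, "trait_architecture"))
  with_seed(seed, {
    if (architecture$h2 == 0) {
      gamma <- numeric(m)
    } else if (architecture$kind == "sparse") {
      n_zero <- round(architecture$pi_null * m)
      n_nonzero <- m - n_zero
      if (n_nonzero < 1L) {
        stop(sprintf(
          "pi_null = %g leaves no nonzero marker at m = %d",
          architecture$pi_null, m
        ), call. = FALSE)
      }
      gamma <- numeric(m)
      nz <- sample.int(m, n_nonzero)
      gamma[nz] <- rnorm(n_nonzero, 0, sqrt(architecture$effect_scale))
      gamma <- gamma * sqrt(m * architecture$effect_scale / sum(gamma^2))
    } else {
      gamma <- rnorm(m, 0, sqrt(architecture$effect_scale))
    }
    marker_effects(0, gamma,
                   marker_ids = sprintf("mk_%0*d", nchar(m), seq_len(m)))
  })
}

#' Simulate phenotypes from genotypes and marker effects
#'
#' Breeding values are `g = Z gamma` (missing genotypes mean-imputed before
#' the product). Residual noise variance is derived from the *realized*
#' variance of `g`: `var(e) = var(g) (1 - h2) / h2`, so the target
#' heritability holds for each generated dataset rather than only in
#' expectation. Fixed effects (sex, birth-year contemporary group, two
#' covariates) are added on top.
#'
#' @param genotypes a [genotype_matrix()].
#' @param effects a [marker_effects()] whose length matches the markers.
#' @param architecture a [trait_architecture()] (supplies `h2`).
#' @param fixed a [fixed_effects_spec()].
#' @param seed RNG seed.
#' @return a `simulated_study` list: `genotypes` (with `birth_year` set),
#'   `true_effects`, `true_breeding_values`, `phenotypes` (data.frame with
#'   columns id, y, sex, birth_year, fatten_days, init_weight),
#'   `components` (`xb`, `e`, `sigma_e2`, `var_g`), `architecture`, `seed`.
#' @export
simulate_phenotypes <- function(genotypes, effects, architecture,
                                fixed = fixed_effects_spec(), seed = 1L) {
  g <- as_geno(genotypes)
  stopifnot(inherits(effects, "marker_effects"),
            inherits(architecture, "trait_architecture"),
            inherits(fixed, "fixed_effects_spec"))
  if (length(effects$gamma) != ncol(g)) {
    stop("effect length must equal the marker count", call. = FALSE)
  }
  n <- nrow(g)
  Z <- if (anyNA(g)) impute_missing(g) else g
  bv <- drop(unclass(Z) %*% effects$gamma)
  var_g <- var(bv)
  h2 <- architecture$h2
  if (h2 == 0) {
    if (var_g > 0) {
      stop("h2 = 0 (null trait) requires all-zero marker effects",
           call. = FALSE)
    }
    sigma_e2 <- 1
  } else if (var_g == 0) {
    stop("degenerate architecture: var(breeding values) is 0 with h2 > 0",
         call. = FALSE)
  } else {
    sigma_e2 <- var_g * (1 - h2) / h2
  }
  with_seed(seed, {
    sex <- sample(fixed$sex_levels, n, replace = TRUE)
    year <- sample(fixed$year_levels, n, replace = TRUE,
                   prob = fixed$year_weights)
    covs <- lapply(fixed$covariates, function(cv) rnorm(n, cv$mean, cv$sd))
    xb <- fixed$sex_coefs[sex] + fixed$year_coefs[as.character(year)]
    for (nm in names(covs)) {
      xb <- xb + fixed$covariates[[nm]]$slope * covs[[nm]]
    }
    xb <- unname(xb)
    e <- if (sigma_e2 > 0) rnorm(n, 0, sqrt(sigma_e2)) else numeric(n)
    y <- xb + bv + e
    pheno <- data.frame(id = rownames(g), y = y, sex = sex,
                        birth_year = year, stringsAsFactors = FALSE)
    for (nm in names(covs)) pheno[[nm]] <- covs[[nm]]
    attr(g, "birth_year") <- as.integer(year)
    structure(list(
      genotypes = g,
      true_effects = effects,
      true_breeding_values = setNames(bv, rownames(g)),
      phenotypes = pheno,
      components = list(xb = xb, e = e, sigma_e2 = sigma_e2, var_g = var_g),
      architecture = architecture,
      fixed = fixed,
      seed = seed
    ), class = "simulated_study")
  })
}

#' One-call dataset simulation
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_effects()] and [simulate_phenotypes()] with sub-seeds derived
#' from `seed` (`seed`, `seed + 1`, `seed + 2`).
#'
#' @inheritParams simulate_genotypes
#' @inheritParams simulate_phenotypes
#' @param architecture a [trait_architecture()].
#' @return a `simulated_study` (see [simulate_phenotypes()]).
#' @export
simulate_study <- function(n, m, architecture = trait_architecture(),
                           fixed = fixed_effects_spec(),
                           maf_range = c(0.05, 0.5), missing_rate = 0,
                           seed = 1L) {
  seed <- check_count(seed, "seed", 0L)
  g <- simulate_genotypes(n, m, maf_range, missing_rate, seed = seed)
  eff <- simulate_effects(m, architecture, seed = seed + 1L)
  simulate_phenotypes(g, eff, architecture, fixed, seed = seed + 2L)
}

#' Realized heritability of a simulated study
#'
#' `var(g) / (var(g) + var(e))` computed from the stored simulation
#' components; the oracle the generator is calibrated against.
#'
#' @param study a `simulated_study`.
#' @return scalar in `[0, 1]`.
#' @export
realized_h2 <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  vg <- var(study$true_breeding_values)
  ve <- var(study$components$e)
  if (vg + ve == 0) return(0)
  vg / (vg + ve)
}
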