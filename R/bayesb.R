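#' MCMC settings for the BayesB sampler
#'
#' Defaults follow the long-chain protocol used in routine genomic
#' prediction: 50,000 iterations, 2,500 burn-in, thinning of 10 (giving
#' 4,750 retained samples) and prior null proportion `pi_null = 0.9`.
#' Slab and residual hyperparameters may be left `NULL`, in which case
#' [bayesb_fit()] calibrates them from the training data (see Details).
#'
#' @details When `s_g` is `NULL` it is solved so that the prior mean
#' genetic variance matches half the phenotypic variance spread over the
#' expected `(1 - pi_null) * m` nonzero loci:
#' `s_g = 0.5 var(y) (nu_g - 2) / (nu_g (1 - pi_null) m vbar)` with `vbar`
#' the mean marker variance. When `s_e` is `NULL`,
#' `s_e = 0.5 var(y) (nu_e - 2) / nu_e`, i.e. a prior mean residual
#' variance of half the phenotypic variance. Both are overridable.
#'
#' @param n_iter total MCMC iterations.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in sample (`>= 1`).
#' @param pi_null prior probability that a marker has exactly zero effect,
#'   in `[0, 1)`.
#' @param seed RNG seed for the chain.
#' @param nu_g,s_g degrees of freedom and scale of the
#'   scaled-inverse-chi-square slab prior on the per-locus variance.
#' @param nu_e,s_e residual-variance prior.
#' @return an `mcmc_settings` list; `n_retained` holds
#'   `floor((n_iter - burn_in) / thin)`.
#' @examples
#' mcmc_settings()$n_retained # 4750
#' @export
mcmc_settings <- function(n_iter = 50000L, burn_in = 2500L, thin = 10L,
                          pi_null = 0.9, seed = 1L, nu_g = 4.2,
                          s_g = NULL, nu_e = 4, s_e = NULL) {
  n_iter <- check_count(n_iter, "n_iter", 1L)
  burn_in <- check_count(burn_in, "burn_in", 0L)
  thin <- check_count(thin, "thin", 1L)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter",
                              call. = FALSE)
  check_scalar(pi_null, "pi_null", 0, 1, strict_upper = TRUE)
  check_scalar(nu_g, "nu_g", 2, strict_lower = TRUE)
  check_scalar(nu_e, "nu_e", 2, strict_lower = TRUE)
  if (!is.null(s_g)) check_scalar(s_g, "s_g", 0, strict_lower = TRUE)
  if (!is.null(s_e)) check_scalar(s_e, "s_e", 0, strict_lower = TRUE)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 pi_null = pi_null, seed = check_count(seed, "seed", 0L),
                 nu_g = nu_g, s_g = s_g, nu_e = nu_e, s_e = s_e,
                 n_retained = (n_iter - burn_in) %/% thin),
            class = "mcmc_settings")
}

#' Fit BayesB marker effects by MCMC
#'
#' Spike-and-slab marker regression: each marker has zero effect with
#' prior probability `pi_null` and otherwise a normal effect with its own
#' scaled-inverse-chi-square variance. Per sweep, the sampler updates the
#' overall mean, then each marker's inclusion indicator (with the effect
#' integrated out, conditional on the locus variance), effect and locus
#' variance, then the residual variance. Fully reproducible given
#' `settings$seed`.
#'
#' @param g_train a complete [genotype_matrix()] of the training
#'   individuals.
#' @param y_star_train training phenotypes (an `adjusted_phenotype` or
#'   numeric vector).
#' @param settings an [mcmc_settings()].
#' @return a `posterior_summary`: `effects` (posterior-mean
#'   [marker_effects()]), `inclusion_prob`, `n_retained`,
#'   `sigma_e_trace`, `settings`.
#' @export
bayesb_fit <- function(g_train, y_star_train, settings = mcmc_settings()) {
  g <- as_geno(g_train)
  stopifnot(inherits(settings, "mcmc_settings"))
  Z <- unclass(g)
  if (anyNA(Z)) stop("run impute_missing() first", call. = FALSE)
  y <- as_response(y_star_train)
  if (length(y) != nrow(Z)) {
    stop("y_star length must match the training genotypes", call. = FALSE)
  }
  if (nrow(Z) < 2L) stop("training set is empty or too small",
                         call. = FALSE)
  m <- ncol(Z)
  vy <- var(y)
  if (vy <= 0) stop("constant training response", call. = FALSE)
  s_e <- settings$s_e %||% (0.5 * vy * (settings$nu_e - 2) / settings$nu_e)
  s_g <- settings$s_g
  if (is.null(s_g)) {
    vbar <- mean(apply(Z, 2L, var))
    if (vbar <= 0) vbar <- 1
    s_g <- 0.5 * vy * (settings$nu_g - 2) /
      (settings$nu_g * (1 - settings$pi_null) * m * vbar)
  }
  fit <- with_seed(settings$seed, bayesb_mcmc(
    Z, y, settings$n_iter, settings$burn_in, settings$thin,
    settings$pi_null, settings$nu_g, s_g, settings$nu_e, s_e
  ))
  structure(list(
    effects = marker_effects(fit$mu, fit$gamma, marker_ids = colnames(Z)),
    inclusion_prob = setNames(fit$inclusion_prob, colnames(Z)),
    n_retained = fit$n_retained,
    sigma_e_trace = fit$sigma_e_trace,
    settings = settings, s_g = s_g, s_e = s_e
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "posterior_summary: %d markers, mean inclusion %.3f, %d retained samples\n",
    length(x$inclusion_prob), mean(x$inclusion_prob), x$n_retained
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
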