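# GBLUP via the mixed-model equations and its marker-space (RR-BLUP) dual.

# Solve V x = b for symmetric positive-definite V, retrying once with a
# small diagonal ridge if the Cholesky factorization fails.
solve_spd <- function(V, B, ridge = 1e-8) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    message(sprintf(
      "coefficient matrix singular; adding ridge %.1e to the diagonal", ridge
    ))
    ch <- chol(V + diag(ridge * mean(diag(V)), nrow(V)))
  }
  backsolve(ch, forwardsolve(t(ch), B))
}

#' GBLUP breeding values from the mixed-model equations
#'
#' Solves Henderson's mixed-model equations for the overall mean `mu`
#' (fixed) and the individual genetic effects `g` with
#' `Var(g) = K sigma_g2`, using the training phenotypes only. Breeding
#' values for non-training individuals come through the kinship blocks
#' linking them to the training set.
#'
#' @param K a [build_grm()] result covering all individuals to predict.
#' @param y_star adjusted phenotypes for the training individuals (an
#'   `adjusted_phenotype` or named/plain numeric vector).
#' @param train indices (integer, logical or character ids) of the
#'   training individuals within `K`.
#' @param vc a `variance_components` with `sigma_e2 > 0`.
#' @param fit_mean estimate `mu` by generalized least squares (default);
#'   `FALSE` fixes `mu = 0`.
#' @return a `gebv` list: `gebv` (named, all individuals in `K`), `mu`,
#'   `method = "gblup"`.
#' @export
gblup_predict <- function(K, y_star, train = seq_along(K$ids), vc,
                          fit_mean = TRUE) {
  stopifnot(inherits(K, "kinship_matrix"),
            inherits(vc, "variance_components"))
  if (vc$sigma_e2 <= 0) stop("sigma_e2 must be strictly positive",
                             call. = FALSE)
  y <- as_response(y_star)
  tr <- resolve_index(train, K$ids)
  if (length(tr) < 1L) stop("training set is empty", call. = FALSE)
  if (length(y) != length(tr)) {
    stop("y_star length must match the training set", call. = FALSE)
  }
  Ktt <- K$K[tr, tr, drop = FALSE]
  V <- vc$sigma_g2 * Ktt + diag(vc$sigma_e2, length(tr))
  if (fit_mean) {
    one <- rep(1, length(tr))
    Vi1y <- solve_spd(V, cbind(one, y))
    mu <- sum(Vi1y[, 2L]) / sum(Vi1y[, 1L])
    alpha <- Vi1y[, 2L] - mu * Vi1y[, 1L]
  } else {
    mu <- 0
    alpha <- drop(solve_spd(V, cbind(y)))
  }
  gebv <- drop(vc$sigma_g2 * K$K[, tr, drop = FALSE] %*% alpha)
  structure(list(gebv = setNames(gebv, K$ids), mu = mu, vc = vc,
                 method = "gblup"),
            class = "gebv")
}

#' RR-BLUP: the marker-space dual of GBLUP
#'
#' Ridge regression of `y*` on all markers with a common per-marker prior
#' variance `sigma_g2 / d`, where `d` is the trace normalizer of the
#' kinship matrix built from the same coded genotypes. With that matching
#' variance the GEBVs `Z gamma-hat` reproduce [gblup_predict()] exactly.
#'
#' @param g a complete [genotype_matrix()] of all individuals to predict.
#' @param y_star training phenotypes, as in [gblup_predict()].
#' @param train training indices within `g`.
#' @param vc a `variance_components`.
#' @param center center marker columns (must match the paired
#'   [build_grm()] call).
#' @param fit_mean as in [gblup_predict()].
#' @return list with `effects` (a [marker_effects()]), `gebv` (named,
#'   all individuals), `mu`, `method = "rrblup"`.
#' @export
rrblup_predict <- function(g, y_star, train = seq_len(nrow(g)), vc,
                           center = FALSE, fit_mean = TRUE) {
  g <- as_geno(g)
  stopifnot(inherits(vc, "variance_components"))
  if (vc$sigma_e2 <= 0) stop("sigma_e2 must be strictly positive",
                             call. = FALSE)
  Z <- unclass(g)
  if (anyNA(Z)) stop("run impute_missing() first", call. = FALSE)
  if (center) Z <- sweep(Z, 2L, colMeans(Z))
  y <- as_response(y_star)
  tr <- resolve_index(train, rownames(Z))
  if (length(y) != length(tr)) {
    stop("y_star length must match the training set", call. = FALSE)
  }
  d <- sum(Z^2) / nrow(Z)
  if (d == 0) stop("degenerate panel: tr(ZZ')/n = 0", call. = FALSE)
  sigma_m2 <- vc$sigma_g2 / d # per-marker effect variance
  Zt <- Z[tr, , drop = FALSE]
  V <- sigma_m2 * tcrossprod(Zt) + diag(vc$sigma_e2, length(tr))
  if (fit_mean) {
    one <- rep(1, length(tr))
    Vi1y <- solve_spd(V, cbind(one, y))
    mu <- sum(Vi1y[, 2L]) / sum(Vi1y[, 1L])
    alpha <- Vi1y[, 2L] - mu * Vi1y[, 1L]
  } else {
    mu <- 0
    alpha <- drop(solve_spd(V, cbind(y)))
  }
  gamma <- drop(sigma_m2 * crossprod(Zt, alpha))
  gebv <- drop(Z %*% gamma)
  structure(list(
    effects = marker_effects(mu, gamma, marker_ids = colnames(Z)),
    gebv = setNames(gebv, rownames(Z)), mu = mu, vc = vc,
    method = "rrblup"
  ), class = "gebv")
}

#' Breeding values from marker effects
#'
#' `GEBV = Z gamma`, the additive sum of marker effects over an
#' individual's genotypes. The intercept is excluded: it shifts every
#' individual equally and is irrelevant for ranking and correlation.
#'
#' @param g a complete [genotype_matrix()].
#' @param effects a [marker_effects()] of matching length.
#' @return named numeric vector of GEBVs.
#' @export
gebv_from_effects <- function(g, effects) {
  g <- as_geno(g)
  stopifnot(inherits(effects, "marker_effects"))
  Z <- unclass(g)
  if (anyNA(Z)) stop("run impute_missing() first", call. = FALSE)
  if (length(effects$gamma) != ncol(Z)) {
    stop(sprintf("effect length (%d) does not match marker count (%d)",
                 length(effects$gamma), ncol(Z)), call. = FALSE)
  }
  setNames(drop(Z %*% effects$gamma), rownames(Z))
}

# Turn logical / character / integer selectors into integer indices.
resolve_index <- function(idx, ids) {
  if (is.logical(idx)) {
    if (length(idx) != length(ids)) {
      stop("logical index length must match the individual count",
           call. = FALSE)
    }
    return(which(idx))
  }
  if (is.character(idx)) {
    out <- match(idx, ids)
    if (anyNA(out)) {
      stop(sprintf("unknown individual id(s): %s",
                   paste(idx[is.na(out)], collapse = ", ")), call. = FALSE)
    }
    return(out)
  }
  as.integer(idx)
}

#' @export
print.gebv <- function(x, ...) {
  cat(sprintf("gebv (%s): %d individuals, mu = %.4g\n",
              x$method, length(x$gebv), x$mu))
  invisible(x)
}
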