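#' Soft-thresholding operator
#'
#' The proximal operator of the L1 penalty:
#' `S(z, t) = sign(z) * max(|z| - t, 0)`. The elementary step of lasso /
#' elastic-net coordinate descent.
#'
#' @param z numeric vector.
#' @param t nonnegative threshold.
#' @return numeric vector.
#' @examples
#' soft_threshold(3, 1)    # 2
#' soft_threshold(-0.5, 1) # 0
#' @export
soft_threshold <- function(z, t) {
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  sign(z) * pmax(abs(z) - t, 0)
}

#' Penalty specification for elastic-net fitting
#'
#' @param alpha mixing parameter in `[0, 1]`: 1 is the lasso, 0 is ridge
#'   regression. `alpha = 0` requires an explicit `lambda` grid (the
#'   automatic grid start `lambda_max` is undefined) and is flagged
#'   experimental.
#' @param lambda optional explicit strictly decreasing penalty grid;
#'   `NULL` builds a log-spaced grid of `n_lambda` values from
#'   `lambda_max = max|X'y| / (n alpha)` (standardized scale) down to
#'   `lambda_max * lambda_min_ratio`.
#' @param n_lambda grid length (default 100).
#' @param lambda_min_ratio default `0.01` when `m > n`, `1e-4` otherwise.
#' @param cv_folds internal cross-validation folds (default 5).
#' @param criterion `"minMSE"` picks the CV-MSE minimizer; `"minMSE_1SE"`
#'   the largest lambda within one standard error of it.
#' @param standardize standardize markers to unit variance internally
#'   (coefficients are reported on the original scale).
#' @param tol convergence tolerance: a path point stops when the largest
#'   coefficient change in a sweep is below `tol * sd(y)`.
#' @param max_sweeps sweep budget per lambda (non-convergence is flagged
#'   per lambda, not fatal).
#' @param seed seed for the internal CV fold split.
#' @return a `penalty_spec` list.
#' @export
penalty_spec <- function(alpha = 1, lambda = NULL, n_lambda = 100L,
                         lambda_min_ratio = NULL, cv_folds = 5L,
                         criterion = c("minMSE", "minMSE_1SE"),
                         standardize = TRUE, tol = 1e-7,
                         max_sweeps = 1e5, seed = 1L) {
  check_scalar(alpha, "alpha", 0, 1)
  criterion <- match.arg(criterion)
  if (!is.null(lambda)) {
    if (any(lambda <= 0) || is.unsorted(rev(lambda), strictly = TRUE)) {
      stop("`lambda` must be a strictly decreasing positive sequence",
           call. = FALSE)
    }
  } else if (alpha == 0) {
    stop(paste("alpha = 0 (pure ridge) requires an explicit `lambda` grid;",
               "the automatic grid start is undefined"), call. = FALSE)
  }
  if (!is.null(lambda_min_ratio)) {
    check_scalar(lambda_min_ratio, "lambda_min_ratio", 0, 1,
                 strict_lower = TRUE, strict_upper = TRUE)
  }
  structure(list(alpha = alpha, lambda = lambda,
                 n_lambda = check_count(n_lambda, "n_lambda", 2L),
                 lambda_min_ratio = lambda_min_ratio,
                 cv_folds = check_count(cv_folds, "cv_folds", 2L),
                 criterion = criterion, standardize = isTRUE(standardize),
                 tol = tol, max_sweeps = as.integer(max_sweeps),
                 seed = check_count(seed, "seed", 0L)),
            class = "penalty_spec")
}

# Standardize X (population scaling, 1/n) and center y; zero-variance
# columns get scale 1 and are zeroed so their coefficients stay 0.
en_prepare <- function(X, y, standardize) {
  n <- nrow(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  if (standardize) {
    xs <- sqrt(colSums(Xc^2) / n)
    dead <- xs <= 0
    xs[dead] <- 1
  } else {
    xs <- rep(1, ncol(X))
    dead <- colSums(Xc^2) == 0
  }
  Xs <- sweep(Xc, 2L, xs, "/")
  if (any(dead)) Xs[, dead] <- 0
  ym <- mean(y)
  list(Xs = Xs, yc = y - ym, xm = xm, xs = xs, ym = ym, n = n)
}

en_lambda_grid <- function(Xs, yc, spec) {
  if (!is.null(spec$lambda)) return(as.numeric(spec$lambda))
  n <- nrow(Xs)
  lmax <- max(abs(crossprod(Xs, yc))) / (n * spec$alpha)
  if (lmax <= 0) stop("constant response: lambda grid undefined",
                      call. = FALSE)
  lmr <- spec$lambda_min_ratio %||%
    (if (ncol(Xs) > n) 1e-2 else 1e-4)
  exp(seq(log(lmax), log(lmax * lmr), length.out = spec$n_lambda))
}

#' Fit an elastic-net coefficient path
#'
#' Cyclic coordinate descent with warm starts down a decreasing lambda
#' grid, minimizing
#' `(1/(2n)) ||y - Z gamma||^2 + lambda sum((1-alpha)/2 gamma^2 + alpha |gamma|)`.
#' Markers are standardized internally (default) and coefficients
#' back-transformed; the intercept is never penalized. Per-sweep objective
#' monotonicity and per-lambda convergence are recorded.
#'
#' @param g_train a complete [genotype_matrix()] (or numeric matrix).
#' @param y_star_train training phenotypes.
#' @param spec a [penalty_spec()].
#' @return an `en_path`: `lambda`, `beta` (m x L, original scale), `a0`
#'   (intercepts), `df` (nonzero counts), `converged`, `obj_increase`,
#'   `spec`.
#' @export
en_fit_path <- function(g_train, y_star_train, spec = penalty_spec()) {
  X <- unclass(as_geno(g_train))
  if (anyNA(X)) stop("run impute_missing() first", call. = FALSE)
  y <- as_response(y_star_train)
  stopifnot(inherits(spec, "penalty_spec"), length(y) == nrow(X))
  pr <- en_prepare(X, y, spec$standardize)
  lambda <- en_lambda_grid(pr$Xs, pr$yc, spec)
  scale_y <- sd(y)
  if (!is.finite(scale_y) || scale_y <= 0) scale_y <- 1
  fit <- elnet_path(pr$Xs, pr$yc, lambda, spec$alpha,
                    spec$tol * scale_y, spec$max_sweeps)
  beta <- fit$beta / pr$xs
  a0 <- pr$ym - drop(crossprod(beta, pr$xm))
  if (!all(fit$converged)) {
    warning(sprintf("coordinate descent did not converge for %d lambda(s)",
                    sum(!fit$converged)), call. = FALSE)
  }
  structure(list(lambda = lambda, beta = beta, a0 = a0,
                 df = colSums(fit$beta != 0), sweeps = fit$sweeps,
                 converged = fit$converged,
                 obj_increase = fit$obj_increase,
                 marker_ids = colnames(X), spec = spec),
            class = "en_path")
}

#' Predict from an elastic-net path
#'
#' @param object an `en_path` (possibly from [en_cv_select()]).
#' @param newx genotype matrix to predict.
#' @param s `"chosen"` (requires [en_cv_select()]), `"all"`, or a lambda
#'   index.
#' @param ... unused.
#' @return numeric vector (single lambda) or matrix (`s = "all"`).
#' @export
predict.en_path <- function(object, newx, s = "chosen", ...) {
  X <- unclass(as_geno(newx))
  if (identical(s, "all")) {
    return(sweep(X %*% object$beta, 2L, object$a0, "+"))
  }
  idx <- if (identical(s, "chosen")) {
    if (is.null(object$index_chosen)) {
      stop("`s = \"chosen\"` requires a path from en_cv_select()",
           call. = FALSE)
    }
    object$index_chosen
  } else {
    as.integer(s)
  }
  drop(X %*% object$beta[, idx] + object$a0[idx])
}

#' Select lambda by internal k-fold cross-validation
#'
#' Builds the lambda grid on the full training set, refits the path on
#' each of `cv_folds` seeded internal folds, and records per-lambda mean
#' squared error and its standard error across folds. `minMSE` picks the
#' MSE minimizer; `minMSE_1SE` the largest (sparsest) lambda whose MSE is
#' within one standard error of the minimum. The final model is the
#' full-training-data fit at the chosen lambda.
#'
#' @inheritParams en_fit_path
#' @return an `en_path` augmented with `cv_mse`, `cv_se`, `index_min`,
#'   `index_1se`, `index_chosen`, `lambda_chosen` and `effects` (a
#'   [marker_effects()] at the chosen lambda).
#' @export
en_cv_select <- function(g_train, y_star_train, spec = penalty_spec()) {
  X <- unclass(as_geno(g_train))
  if (anyNA(X)) stop("run impute_missing() first", call. = FALSE)
  y <- as_response(y_star_train)
  stopifnot(inherits(spec, "penalty_spec"), length(y) == nrow(X))
  n <- nrow(X)
  if (n < spec$cv_folds) {
    stop("training set smaller than the fold count", call. = FALSE)
  }
  path <- en_fit_path(X, y, spec)
  lambda <- path$lambda
  plan <- kfold_split(seq_len(n), k = spec$cv_folds, seed = spec$seed)
  folds <- plan$folds
  mse <- matrix(NA_real_, spec$cv_folds, length(lambda))
  sub <- spec
  sub$lambda <- lambda
  for (f in seq_len(spec$cv_folds)) {
    test <- folds == f
    ytr <- y[!test]
    if (var(ytr) == 0) {
      warning(sprintf("internal CV fold %d has constant response; skipped",
                      f), call. = FALSE)
      next
    }
    pf <- en_fit_path(X[!test, , drop = FALSE], ytr, sub)
    pred <- sweep(X[test, , drop = FALSE] %*% pf$beta, 2L, pf$a0, "+")
    mse[f, ] <- colMeans((y[test] - pred)^2)
  }
  used <- rowSums(is.na(mse)) == 0
  if (!any(used)) stop("all internal CV folds degenerate", call. = FALSE)
  cv_mse <- colMeans(mse[used, , drop = FALSE])
  cv_se <- apply(mse[used, , drop = FALSE], 2L, sd) / sqrt(sum(used))
  index_min <- which.min(cv_mse)
  within_1se <- which(cv_mse <= cv_mse[index_min] + cv_se[index_min])
  index_1se <- min(within_1se) # lambdas are decreasing: smallest index wins
  index_chosen <- if (spec$criterion == "minMSE") index_min else index_1se
  path$cv_mse <- cv_mse
  path$cv_se <- cv_se
  path$cv_folds_used <- sum(used)
  path$index_min <- index_min
  path$index_1se <- index_1se
  path$index_chosen <- index_chosen
  path$lambda_chosen <- lambda[index_chosen]
  path$effects <- marker_effects(path$a0[index_chosen],
                                 path$beta[, index_chosen],
                                 marker_ids = path$marker_ids)
  path
}

#' @export
print.en_path <- function(x, ...) {
  cat(sprintf("en_path: alpha = %g, %d lambdas", x$spec$alpha,
              length(x$lambda)))
  if (!is.null(x$index_chosen)) {
    cat(sprintf(", chosen lambda = %.4g (%s, %d nonzero)",
                x$lambda_chosen, x$spec$criterion, x$df[x$index_chosen]))
  }
  cat("\n")
  invisible(x)
}
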