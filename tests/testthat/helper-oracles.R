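# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the code paths they check: dense-matrix REML, an
# exhaustive sign-pattern lasso solver, and KKT condition checks.

# A small complete dataset with genotypes, adjusted phenotype and truth.
make_fixture <- function(n = 120, m = 80, kind = "polygenic", h2 = 0.5,
                         pi_null = 0, missing_rate = 0, seed = 1) {
  arch <- trait_architecture(kind, h2 = h2, pi_null = pi_null)
  st <- simulate_study(n, m, arch, missing_rate = missing_rate, seed = seed)
  adj <- adjust_phenotype(st$phenotypes)
  list(study = st, adj = adj, Z = impute_missing(st$genotypes))
}

# Restricted log-likelihood of y = 1*mu + g + e, g ~ N(0, K*sg2),
# evaluated densely: -(1/2)[(n-1)log(2pi) + log|V| + log(1'V^-1 1)
# - log(n) + y'Py]. Matches the density of any orthonormal contrast basis.
dense_reml_loglik <- function(K, y, sg2, se2) {
  n <- length(y)
  V <- sg2 * K + diag(se2, n)
  Vi <- solve(V)
  one <- rep(1, n)
  xvx <- drop(crossprod(one, Vi %*% one))
  P <- Vi - (Vi %*% one %*% t(one) %*% Vi) / xvx
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * ((n - 1) * log(2 * pi) + ld + log(xvx) - log(n) +
            drop(crossprod(y, P %*% y)))
}

# Profile the dense REML over the genetic scale at fixed h2 by 1-D search.
dense_reml_profile <- function(K, y, h2) {
  delta <- (1 - h2) / h2
  opt <- optimize(function(lsg2) {
    sg2 <- exp(lsg2)
    dense_reml_loglik(K, y, sg2, delta * sg2)
  }, interval = c(-10, 10), maximum = TRUE, tol = 1e-10)
  opt$objective
}

# Exhaustive elastic-net solver for tiny problems: enumerate all
# active-set/sign patterns, solve the stationarity equations and keep the
# solution satisfying the KKT conditions. X standardized, y centered;
# objective (1/(2n))||y - Xb||^2 + lam*((1-a)/2 ||b||^2 + a ||b||_1).
enumerate_enet <- function(X, y, lam, alpha) {
  n <- nrow(X)
  m <- ncol(X)
  G <- crossprod(X) / n
  xy <- drop(crossprod(X, y)) / n
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), m)))
  for (r in seq_len(nrow(signs))) {
    s <- signs[r, ]
    A <- which(s != 0)
    b <- numeric(m)
    if (length(A)) {
      M <- G[A, A, drop = FALSE] + diag(lam * (1 - alpha), length(A))
      bA <- tryCatch(solve(M, xy[A] - lam * alpha * s[A]),
                     error = function(e) NULL)
      if (is.null(bA)) next
      if (any(sign(bA) != s[A])) next
      b[A] <- bA
    }
    grad <- xy - G %*% b # X'r/n
    if (length(A) &&
        any(abs(grad[A] - lam * ((1 - alpha) * b[A] + alpha * s[A])) >
            1e-9)) next
    inactive <- setdiff(seq_len(m), A)
    if (length(inactive) && any(abs(grad[inactive]) > lam * alpha + 1e-9)) {
      next
    }
    return(b)
  }
  stop("enumeration oracle found no KKT point")
}

# Max KKT violation of an elastic-net solution on the standardized scale.
enet_kkt_violation <- function(X, y, b, lam, alpha) {
  n <- nrow(X)
  grad <- drop(crossprod(X, y - X %*% b)) / n
  active <- b != 0
  v <- 0
  if (any(active)) {
    v <- max(abs(grad[active] - lam * ((1 - alpha) * b[active] +
                                         alpha * sign(b[active]))))
  }
  if (any(!active)) {
    v <- max(v, max(pmax(abs(grad[!active]) - lam * alpha, 0)))
  }
  v
}

# Run code under a local seed without disturbing the global RNG stream.
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  code
}

# Standardize columns like the package does (mean 0, mean square 1).
std_cols <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  s <- sqrt(colSums(Xc^2) / nrow(X))
  s[s == 0] <- 1
  sweep(Xc, 2L, s, "/")
}
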