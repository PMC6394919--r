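#' Build the genomic relationship matrix
#'
#' With the coded genotype matrix `Z` (entries `1/0/-1` for `11/12/22`),
#' the kinship matrix is `K = Z Z' / d` with the trace normalizer
#' `d = tr(Z Z') / n`, which forces `mean(diag(K)) = 1`. By default `Z`
#' is used exactly as coded (uncentered); `center = TRUE` subtracts column
#' means first, giving the allele-frequency-centered form whose variance
#' components match the usual centered definition of genetic variance (see
#' the methods vignette for when this matters).
#'
#' @param g a complete [genotype_matrix()] (run [impute_missing()] first).
#' @param center subtract marker means before forming `K` (default
#'   `FALSE`).
#' @return a `kinship_matrix`: list with `K` (n x n, dimnames = ids), `d`,
#'   `ids`, `center`.
#' @examples
#' K <- build_grm(genotype_matrix(rbind(c(1, -1), c(-1, 1))))
#' K$K # [[1, -1], [-1, 1]]
#' @export
build_grm <- function(g, center = FALSE) {
  g <- as_geno(g)
  Z <- unclass(g)
  if (anyNA(Z)) {
    stop("genotype matrix has missing entries; run impute_missing() first",
         call. = FALSE)
  }
  if (ncol(Z) < 1L) stop("at least one marker required", call. = FALSE)
  if (center) Z <- sweep(Z, 2L, colMeans(Z))
  n <- nrow(Z)
  d <- sum(Z^2) / n
  if (d == 0) {
    stop("degenerate panel: tr(ZZ')/n = 0 (all coded genotypes zero)",
         call. = FALSE)
  }
  K <- tcrossprod(Z) / d
  structure(list(K = K, d = d, ids = rownames(Z), center = center),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d individuals, d = %.4g, %s\n",
              length(x$ids), x$d,
              if (x$center) "centered" else "uncentered"))
  invisible(x)
}

# Subset a kinship matrix to a set of individuals (d is kept: it is a
# property of the panel, not of the subset).
subset_kinship <- function(K, idx) {
  stopifnot(inherits(K, "kinship_matrix"))
  structure(list(K = K$K[idx, idx, drop = FALSE], d = K$d,
                 ids = K$ids[idx], center = K$center),
            class = "kinship_matrix")
}
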