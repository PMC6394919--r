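#' Construct a genotype matrix
#'
#' A genotype matrix stores additively coded diploid SNP calls for `n`
#' individuals (rows) at `m` markers (columns). Calls are coded
#' `1`, `0`, `-1` for the three genotypes `11`, `12`, `22` (minor-allele
#' dosage minus one); sporadic missing calls are `NA`. Fractional entries
#' only arise after [impute_missing()], which flags the result with the
#' `imputed` attribute.
#'
#' @param values numeric matrix, entries in `{-1, 0, 1, NA}`.
#' @param individual_ids unique row identifiers (defaults to rownames).
#' @param marker_ids unique column identifiers (defaults to colnames).
#' @param birth_year optional integer vector of birth years per individual,
#'   used by [generation_split()].
#' @return a `genotype_matrix`: a numeric matrix with dimnames and an
#'   optional `birth_year` attribute.
#' @examples
#' g <- genotype_matrix(rbind(c(1, 0), c(-1, NA)))
#' @export
genotype_matrix <- function(values, individual_ids = rownames(values),
                            marker_ids = colnames(values),
                            birth_year = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  bad <- !is.na(values) & !(values %in% c(-1, 0, 1))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "genotype codes must be -1, 0, 1 or NA; found %g at row %d, column %d",
      values[bad][1L], idx[1L], idx[2L]
    ), call. = FALSE)
  }
  new_genotype_matrix(values, individual_ids, marker_ids, birth_year)
}

# Constructor without the entry-alphabet check (used for imputed matrices).
new_genotype_matrix <- function(values, individual_ids = rownames(values),
                                marker_ids = colnames(values),
                                birth_year = NULL, imputed = FALSE) {
  n <- nrow(values)
  m <- ncol(values)
  if (is.null(individual_ids)) {
    individual_ids <- sprintf("ind_%0*d", nchar(n), seq_len(n))
  }
  if (is.null(marker_ids)) {
    marker_ids <- sprintf("mk_%0*d", nchar(m), seq_len(m))
  }
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (length(individual_ids) != n || anyDuplicated(individual_ids)) {
    stop("individual ids must be unique and match the row count",
         call. = FALSE)
  }
  if (length(marker_ids) != m || anyDuplicated(marker_ids)) {
    stop("marker ids must be unique and match the column count",
         call. = FALSE)
  }
  dimnames(values) <- list(individual_ids, marker_ids)
  if (!is.null(birth_year)) {
    if (length(birth_year) != n) {
      stop("`birth_year` must have one entry per individual", call. = FALSE)
    }
    attr(values, "birth_year") <- as.integer(birth_year)
  }
  attr(values, "imputed") <- isTRUE(imputed)
  class(values) <- c("genotype_matrix", class(matrix()))
  values
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d markers (%.2f%% missing%s)\n",
    nrow(x), ncol(x), 100 * mean(is.na(x)),
    if (isTRUE(attr(x, "imputed"))) ", imputed" else ""
  ))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  by <- attr(x, "birth_year")
  imputed <- attr(x, "imputed")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    if (!is.null(by)) {
      keep <- if (missing(i)) seq_len(nrow(unclass(x))) else i
      by <- if (is.character(keep)) by[match(keep, rownames(x))] else by[keep]
    }
    out <- new_genotype_matrix(out, birth_year = by, imputed = imputed)
  }
  out
}

# Coerce a plain matrix for use where a genotype matrix is expected.
as_geno <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x)
  if (is.matrix(x) && is.numeric(x)) return(new_genotype_matrix(x))
  stop("expected a genotype matrix", call. = FALSE)
}

#' Birth years carried by a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @return integer vector named by individual id, or `NULL` if absent.
#' @export
birth_years <- function(g) {
  by <- attr(g, "birth_year")
  if (is.null(by)) return(NULL)
  names(by) <- rownames(g)
  by
}

#' Construct a marker-effects object
#'
#' Holds an intercept `mu` and one additive effect per marker; the object a
#' Bayesian or penalized marker regression estimates and that
#' [gebv_from_effects()] turns into breeding values.
#'
#' @param mu scalar intercept.
#' @param gamma numeric vector of per-marker additive effects.
#' @param marker_ids optional marker names (defaults to `names(gamma)`).
#' @return a `marker_effects` list with elements `mu` and `gamma`.
#' @export
marker_effects <- function(mu, gamma, marker_ids = names(gamma)) {
  check_scalar(mu, "mu")
  force(marker_ids)
  if (!is.numeric(gamma) || length(gamma) < 1L) {
    stop("`gamma` must be a non-empty numeric vector", call. = FALSE)
  }
  gamma <- as.numeric(gamma)
  if (!is.null(marker_ids)) {
    if (length(marker_ids) != length(gamma)) {
      stop("`marker_ids` must match the effect count", call. = FALSE)
    }
    names(gamma) <- as.character(marker_ids)
  }
  structure(list(mu = as.numeric(mu), gamma = gamma),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  nz <- sum(x$gamma != 0)
  cat(sprintf("marker_effects: %d markers (%d nonzero), mu = %.4g\n",
              length(x$gamma), nz, x$mu))
  invisible(x)
}
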