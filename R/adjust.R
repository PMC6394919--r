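#' Pre-adjust phenotypes for fixed effects
#'
#' Fits `y ~ intercept + factors + covariates` by ordinary least squares
#' (treatment coding, first level as reference) and returns the residual
#' `y*`, the sole response used by all downstream predictors. Rows with
#' missing values in any used column are dropped and recorded.
#'
#' @param pheno data.frame of raw phenotypes and fixed-effect columns.
#' @param response name of the phenotype column (default `"y"`).
#' @param factors character vector of contemporary-group columns, coerced
#'   to factors (default `c("sex", "birth_year")`).
#' @param covariates character vector of continuous columns fitted with
#'   global slopes (default `c("fatten_days", "init_weight")`).
#' @param id_col name of the individual-id column.
#' @return an `adjusted_phenotype`: list with `y_star` (named residuals,
#'   zero mean), `coefficients`, `n`, `dropped_ids`, `formula`.
#' @examples
#' ph <- data.frame(id = 1:6, y = c(10, 10, 10, 12, 12, 12),
#'                  sex = rep(c("A", "B"), each = 3))
#' adjust_phenotype(ph, factors = "sex", covariates = character())
#' @export
adjust_phenotype <- function(pheno, response = "y",
                             factors = c("sex", "birth_year"),
                             covariates = c("fatten_days", "init_weight"),
                             id_col = "id") {
  stopifnot(is.data.frame(pheno))
  used <- c(id_col, response, factors, covariates)
  missing_cols <- setdiff(used, names(pheno))
  if (length(missing_cols)) {
    stop(sprintf("phenotype table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  keep <- stats::complete.cases(pheno[used])
  dropped <- as.character(pheno[[id_col]][!keep])
  df <- pheno[keep, used, drop = FALSE]
  if (nrow(df) < length(factors) + length(covariates) + 2L) {
    stop("too few complete observations to fit the adjustment model",
         call. = FALSE)
  }
  for (f in factors) df[[f]] <- factor(df[[f]])
  for (cv in covariates) df[[cv]] <- as.numeric(df[[cv]])
  rhs <- c(factors, covariates)
  fml <- stats::reformulate(if (length(rhs)) rhs else "1",
                            response = response)
  fit <- lm(fml, data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop(sprintf("rank-deficient adjustment design; collinear column(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")),
         call. = FALSE)
  }
  y_star <- setNames(unname(residuals(fit)), as.character(df[[id_col]]))
  structure(list(y_star = y_star, coefficients = cf, n = nrow(df),
                 dropped_ids = dropped, formula = fml),
            class = "adjusted_phenotype")
}

#' @export
print.adjusted_phenotype <- function(x, ...) {
  cat(sprintf(
    "adjusted_phenotype: %d individuals, sd(y*) = %.4g (%d dropped)\n",
    x$n, sd(x$y_star), length(x$dropped_ids)
  ))
  invisible(x)
}
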