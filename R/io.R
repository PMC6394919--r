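# Text-format readers and writers. Genotypes travel as TSV (rows =
# individuals, first column `id`, marker ids in the header, NA for
# missing); phenotypes as CSV; results as CSV/JSON. Binary chip formats
# are import dialects, not native storage.

#' Read a genotype matrix from a delimited text file
#'
#' Two dialects are supported: `"tsv"` (native, entries `-1/0/1`, `NA`
#' missing) and `"plink_additive"` (additive 0/1/2 dosage text export,
#' mapped to `-1/0/1` by subtracting 1). Any entry outside the dialect's
#' alphabet is a parse error reporting the line and column.
#'
#' @param path file path; first column must be `id`, remaining columns are
#'   markers.
#' @param dialect `"tsv"` or `"plink_additive"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink_additive")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  dt <- data.table::fread(path, sep = if (dialect == "tsv") "\t" else "auto",
                          header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(dt) < 2L || names(dt)[1L] != "id") {
    stop("malformed genotype file: first column must be `id`",
         call. = FALSE)
  }
  ids <- as.character(dt[[1L]])
  vals <- suppressWarnings(
    vapply(dt[-1L], as.numeric, numeric(nrow(dt)))
  )
  if (nrow(dt) == 1L) vals <- matrix(vals, nrow = 1L,
                                     dimnames = list(NULL, names(dt)[-1L]))
  alphabet <- if (dialect == "tsv") c(-1, 0, 1) else c(0, 1, 2)
  raw_na <- is.na(as.matrix(dt[-1L]))
  bad <- (!is.na(vals) & !(vals %in% alphabet)) | (is.na(vals) & !raw_na)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid %s genotype code at line %d, column `%s`",
      dialect, idx[1L] + 1L, names(dt)[-1L][idx[2L]]
    ), call. = FALSE)
  }
  if (dialect == "plink_additive") vals <- vals - 1
  genotype_matrix(vals, individual_ids = ids, marker_ids = names(dt)[-1L])
}

#' Write a genotype matrix as TSV
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  g <- as_geno(g)
  df <- data.frame(id = rownames(g), unclass(g), check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a phenotype table (CSV)
#'
#' @param path CSV with at least columns `id` and the phenotype.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  if (!"id" %in% names(df)) stop("phenotype table needs an `id` column",
                                 call. = FALSE)
  df$id <- as.character(df$id)
  df
}

#' Write a phenotype table (CSV)
#' @param pheno data.frame.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  data.table::fwrite(pheno, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Write the simulation truth file (JSON)
#'
#' Stores true effects, breeding values and the realized heritability of a
#' `simulated_study` so tests can use them as oracles.
#'
#' @param study a `simulated_study`.
#' @param path output path.
#' @export
write_truth_json <- function(study, path) {
  stopifnot(inherits(study, "simulated_study"))
  jsonlite::write_json(list(
    mu = study$true_effects$mu,
    effects = as.list(study$true_effects$gamma),
    breeding_values = as.list(study$true_breeding_values),
    h2_target = study$architecture$h2,
    h2_realized = realized_h2(study),
    sigma_e2 = study$components$sigma_e2,
    seed = study$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a per-marker QC report (CSV)
#' @param report data.frame from [filter_markers()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  data.table::fwrite(report, path, quote = FALSE)
  invisible(path)
}

#' Write a kinship matrix as dense CSV with id header
#' @param K a [build_grm()] result.
#' @param path output path.
#' @export
write_grm <- function(K, path) {
  stopifnot(inherits(K, "kinship_matrix"))
  df <- data.frame(id = K$ids, K$K, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", K$ids)
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Write GEBVs as CSV (id, gebv)
#' @param gebv named numeric vector (or `gebv` object).
#' @param path output path.
#' @export
write_gebv <- function(gebv, path) {
  v <- if (inherits(gebv, "gebv")) gebv$gebv else gebv
  data.table::fwrite(
    data.frame(id = names(v), gebv = as.numeric(v),
               stringsAsFactors = FALSE),
    path, quote = FALSE
  )
  invisible(path)
}

#' Write an accuracy report as CSV
#' @param report an `accuracy_report` from [run_comparison()].
#' @param path output path.
#' @export
write_accuracy_report <- function(report, path) {
  stopifnot(inherits(report, "accuracy_report"))
  df <- report$summary
  df$h2 <- report$h2
  df$fold_checksum <- report$fold_checksum
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Write variance components as JSON
#' @param vc a `variance_components`.
#' @param path output path.
#' @export
write_variance_components <- function(vc, path) {
  stopifnot(inherits(vc, "variance_components"))
  jsonlite::write_json(list(
    sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2, h2 = vc$h2,
    se_h2 = vc$se_h2, loglik = vc$loglik, boundary = vc$boundary
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write BayesB posterior summaries
#'
#' Effect summary CSV (marker, posterior mean, inclusion probability) and,
#' optionally, the retained residual-variance trace.
#'
#' @param fit a `posterior_summary` from [bayesb_fit()].
#' @param path effect-summary CSV path.
#' @param trace_path optional CSV path for the `sigma_e2` trace.
#' @export
write_posterior_summary <- function(fit, path, trace_path = NULL) {
  stopifnot(inherits(fit, "posterior_summary"))
  data.table::fwrite(data.frame(
    marker = names(fit$effects$gamma),
    posterior_mean = unname(fit$effects$gamma),
    inclusion_prob = unname(fit$inclusion_prob),
    stringsAsFactors = FALSE
  ), path, quote = FALSE)
  if (!is.null(trace_path)) {
    data.table::fwrite(data.frame(sample = seq_along(fit$sigma_e_trace),
                                  sigma_e2 = fit$sigma_e_trace),
                       trace_path, quote = FALSE)
  }
  invisible(path)
}

#' Write an elastic-net path summary
#'
#' Per-lambda CSV with the cross-validated error curve (when present) and
#' nonzero counts.
#'
#' @param path_obj an `en_path` (ideally from [en_cv_select()]).
#' @param path output CSV path.
#' @export
write_en_path <- function(path_obj, path) {
  stopifnot(inherits(path_obj, "en_path"))
  df <- data.frame(lambda = path_obj$lambda,
                   n_nonzero = path_obj$df,
                   converged = path_obj$converged)
  if (!is.null(path_obj$cv_mse)) {
    df$cv_mse <- path_obj$cv_mse
    df$cv_se <- path_obj$cv_se
    df$chosen <- seq_along(path_obj$lambda) == path_obj$index_chosen
  }
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}
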