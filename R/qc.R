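#' Quality-control thresholds for SNP panels
#'
#' Defaults follow common practice for medium-density cattle panels: keep
#' markers with call rate strictly above 0.95, minor allele frequency
#' strictly above 0.05 and a Hardy-Weinberg equilibrium chi-square p-value
#' strictly above 1e-5; drop samples with strictly more than 10% missing
#' calls. All comparisons are strict inequalities.
#'
#' @param min_call_rate,min_maf,hwe_p_floor,max_sample_missing thresholds
#'   in `[0, 1]`.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.05,
                          hwe_p_floor = 1e-5, max_sample_missing = 0.10) {
  for (nm in c("min_call_rate", "min_maf", "hwe_p_floor",
               "max_sample_missing")) {
    check_scalar(get(nm), nm, 0, 1)
  }
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor,
                 max_sample_missing = max_sample_missing),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium test p-value
#'
#' Pearson chi-square goodness-of-fit of the observed genotype counts
#' against Hardy-Weinberg proportions at the observed allele frequency,
#' with 1 degree of freedom. Monomorphic markers return `p = 1` by
#' convention. All arguments are vectorized.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (`11`, `12`, `22`).
#' @return p-values in `[0, 1]`.
#' @examples
#' hwe_pvalue(25, 50, 25) # 1: perfect HWE
#' hwe_pvalue(30, 40, 30) # chi-square 4 on 1 df
#' @export
hwe_pvalue <- function(n_AA, n_Aa, n_aa) {
  counts <- cbind(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || anyNA(counts)) {
    stop("genotype counts must be nonnegative", call. = FALSE)
  }
  n <- rowSums(counts)
  if (any(n < 1)) stop("at least one called genotype required", call. = FALSE)
  p <- (2 * counts[, 1L] + counts[, 2L]) / (2 * n)
  expd <- cbind(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
  mono <- p == 0 | p == 1
  stat <- rep(0, length(n))
  ok <- !mono
  if (any(ok)) {
    stat[ok] <- rowSums((counts[ok, , drop = FALSE] -
                           expd[ok, , drop = FALSE])^2 /
                          expd[ok, , drop = FALSE])
  }
  out <- pchisq(stat, df = 1, lower.tail = FALSE)
  out[mono] <- 1
  unname(out)
}

# Per-marker summary used by filter_markers() and tests.
marker_qc_stats <- function(g) {
  g <- as_geno(g)
  n <- nrow(g)
  gm <- unclass(g)
  n_AA <- colSums(gm == 1, na.rm = TRUE)
  n_Aa <- colSums(gm == 0, na.rm = TRUE)
  n_aa <- colSums(gm == -1, na.rm = TRUE)
  called <- n_AA + n_Aa + n_aa
  p_hat <- ifelse(called > 0, (2 * n_AA + n_Aa) / (2 * called), NA_real_)
  hwe <- rep(NA_real_, length(called))
  ok <- called > 0
  if (any(ok)) hwe[ok] <- hwe_pvalue(n_AA[ok], n_Aa[ok], n_aa[ok])
  data.frame(
    marker = colnames(g),
    call_rate = called / n,
    maf = pmin(p_hat, 1 - p_hat),
    hwe_p = hwe,
    stringsAsFactors = FALSE
  )
}

#' Filter markers on call rate, MAF and HWE
#'
#' Keeps markers whose call rate, minor allele frequency and HWE p-value
#' all lie strictly above the thresholds; statistics are computed on the
#' raw (pre-imputation) calls. The report covers every input marker with
#' its statistics and the first failing criterion.
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (surviving markers) and `report`
#'   (data.frame: marker, call_rate, maf, hwe_p, pass, reason).
#' @export
filter_markers <- function(g, thresholds = qc_thresholds()) {
  g <- as_geno(g)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (ncol(g) < 1L || nrow(g) < 1L) stop("empty genotype matrix",
                                         call. = FALSE)
  st <- marker_qc_stats(g)
  fail_cr <- !(st$call_rate > thresholds$min_call_rate)
  fail_maf <- !(is.finite(st$maf) & st$maf > thresholds$min_maf)
  fail_hwe <- !(is.finite(st$hwe_p) & st$hwe_p > thresholds$hwe_p_floor)
  st$pass <- !(fail_cr | fail_maf | fail_hwe)
  st$reason <- ""
  st$reason[fail_hwe] <- "hwe_fail"
  st$reason[fail_maf] <- "low_maf"
  st$reason[fail_cr] <- "low_call_rate"
  if (!any(st$pass)) {
    stop("all markers removed by QC: downstream models are undefined",
         call. = FALSE)
  }
  list(genotypes = g[, st$pass, drop = FALSE], report = st)
}

#' Filter samples on missing-genotype fraction
#'
#' Removes individuals with strictly more than `max_sample_missing`
#' missing calls; survivor order is preserved.
#'
#' @inheritParams filter_markers
#' @return the filtered [genotype_matrix()].
#' @export
filter_samples <- function(g, thresholds = qc_thresholds()) {
  g <- as_geno(g)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (nrow(g) < 1L) stop("empty genotype matrix", call. = FALSE)
  miss <- rowMeans(is.na(unclass(g)))
  keep <- !(miss > thresholds$max_sample_missing)
  if (!any(keep)) {
    stop("all samples removed by QC: downstream models are undefined",
         call. = FALSE)
  }
  g[keep, , drop = FALSE]
}

#' Impute sporadic missing genotypes by marker means
#'
#' Each missing entry is replaced by the mean coded genotype of its marker
#' (a value in `[-1, 1]`, equal to `2 * MAF - 1` up to sampling); observed
#' calls are untouched. This preserves per-marker allele-frequency
#' expectations, which is all the downstream additive models use.
#'
#' @param g a [genotype_matrix()]; every marker needs at least one call.
#' @return a complete [genotype_matrix()] (fractional entries allowed),
#'   flagged with attribute `imputed`.
#' @export
impute_missing <- function(g) {
  g <- as_geno(g)
  gm <- unclass(g)
  if (!anyNA(gm)) {
    attr(g, "imputed") <- TRUE
    return(g)
  }
  mu <- colMeans(gm, na.rm = TRUE)
  if (anyNA(mu) || any(!is.finite(mu))) {
    bad <- colnames(g)[!is.finite(mu)][1L]
    stop(sprintf(
      "marker `%s` has no called genotypes; run filter_markers() first", bad
    ), call. = FALSE)
  }
  idx <- which(is.na(gm))
  gm[idx] <- mu[(idx - 1L) %/% nrow(gm) + 1L]
  new_genotype_matrix(gm, birth_year = attr(g, "birth_year"), imputed = TRUE)
}

#' Run the full genotype QC pipeline
#'
#' Fixed order: marker filters, then the sample filter, then mean
#' imputation.
#'
#' @inheritParams filter_markers
#' @param impute impute after filtering (default `TRUE`).
#' @return list with `genotypes`, `marker_report`, `removed_samples`.
#' @export
run_qc <- function(g, thresholds = qc_thresholds(), impute = TRUE) {
  mk <- filter_markers(g, thresholds)
  before <- rownames(mk$genotypes)
  gs <- filter_samples(mk$genotypes, thresholds)
  out <- if (impute) impute_missing(gs) else gs
  list(genotypes = out, marker_report = mk$report,
       removed_samples = setdiff(before, rownames(gs)))
}
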