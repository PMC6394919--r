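# Run configuration and the end-to-end pipeline:
# (simulate) -> qc -> adjust -> compare.

config_schema <- function() {
  list(
    seed = NULL, log_level = NULL,
    paths = list(genotypes = NULL, phenotypes = NULL, output_dir = NULL,
                 genotype_dialect = NULL),
    simulate = list(n = NULL, m = NULL, maf_range = NULL,
                    missing_rate = NULL, seed = NULL,
                    architecture = list(kind = NULL, pi_null = NULL,
                                        h2 = NULL, effect_scale = NULL)),
    qc = list(min_call_rate = NULL, min_maf = NULL, hwe_p_floor = NULL,
              max_sample_missing = NULL),
    adjust = list(response = NULL, factors = NULL, covariates = NULL),
    methods = NA, # free method names; entries validated separately
    validation = list(scheme = NULL, k = NULL, cutoff_year = NULL,
                      seed = NULL)
  )
}

method_keys <- c("method", "alpha", "n_lambda", "lambda_min_ratio",
                 "cv_folds", "criterion", "pi_null", "n_iter", "burn_in",
                 "thin")

check_keys <- function(x, schema, prefix = "") {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown)) {
    stop(sprintf("unknown config key: %s%s", prefix, unknown[1L]),
         call. = FALSE)
  }
  for (nm in names(x)) {
    if (is.list(schema[[nm]]) && is.list(x[[nm]])) {
      check_keys(x[[nm]], schema[[nm]], paste0(prefix, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Validate a run configuration
#'
#' Configurations are nested lists (typically read from JSON). Unknown
#' keys anywhere are rejected so typos fail fast; each method block must
#' name a known method kind.
#'
#' @param config nested list.
#' @return the config, invisibly, after validation.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  check_keys(config, config_schema())
  if (!is.null(config$methods)) {
    for (nm in names(config$methods)) {
      mth <- config$methods[[nm]]
      if (is.null(mth$method) ||
          !mth$method %in% c("gblup", "bayesb", "en")) {
        stop(sprintf("method `%s` must set method to gblup, bayesb or en",
                     nm), call. = FALSE)
      }
      unknown <- setdiff(names(mth), method_keys)
      if (length(unknown)) {
        stop(sprintf("unknown config key: methods.%s.%s", nm, unknown[1L]),
             call. = FALSE)
      }
    }
  }
  if (!is.null(config$validation$scheme) &&
      !config$validation$scheme %in% c("kfold", "generation")) {
    stop("validation.scheme must be `kfold` or `generation`",
         call. = FALSE)
  }
  invisible(config)
}

#' Read a run configuration from JSON
#'
#' @param path JSON file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  validate_run_config(cfg)
  cfg
}

pipeline_log <- function(state, level, msg) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), msg)
  cat(line, "\n", file = state$log_path, append = TRUE, sep = "")
  if (identical(state$log_level, "debug") ||
      (identical(state$log_level, "info") && level != "debug")) {
    message(line)
  }
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) data simulation, genotype QC, phenotype
#' adjustment and the method comparison described by `config`, writing all
#' artifacts (resolved config, QC report, adjusted phenotypes, per-method
#' GEBVs, accuracy report, run log, MANIFEST with input checksums) to the
#' output directory. Identical configs and seeds reproduce every report
#' byte-for-byte; only the log carries timestamps. On a stage error the
#' MANIFEST records the failing stage and partial artifacts are retained.
#'
#' @param config a validated configuration (see [validate_run_config()])
#'   or a path to a JSON config.
#' @param output_dir overrides `config$paths$output_dir`.
#' @param stages subset of `c("data", "qc", "adjust", "compare")` to run
#'   (earlier artifacts are read from the output directory if needed).
#' @return invisibly, a list with `files`, `report` (when the compare
#'   stage ran) and `status` (0 on success).
#' @export
run_pipeline <- function(config, output_dir = NULL,
                         stages = c("data", "qc", "adjust", "compare")) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out <- output_dir %||% config$paths$output_dir %||%
    stop("no output directory configured", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  state <- list(log_path = file.path(out, "run.log"),
                log_level = config$log_level %||% "warn")
  files <- character()
  report <- NULL
  stage_now <- "setup"
  status <- tryCatch({
    cfg_path <- file.path(out, "resolved_config.json")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    files <- c(files, cfg_path)
    pipeline_log(state, "info", sprintf(
      "genopred %s pipeline start (seed %d)",
      as.character(utils::packageVersion("genopred")), seed
    ))

    geno <- NULL
    pheno <- NULL

    if ("data" %in% stages) {
      stage_now <- "data"
      if (!is.null(config$simulate)) {
        sim <- config$simulate
        arch <- do.call(trait_architecture, sim$architecture %||% list())
        study <- simulate_study(
          n = sim$n, m = sim$m, architecture = arch,
          maf_range = unlist(sim$maf_range %||% c(0.05, 0.5)),
          missing_rate = sim$missing_rate %||% 0,
          seed = sim$seed %||% seed
        )
        geno <- study$genotypes
        pheno <- study$phenotypes
        files <- c(files,
                   write_genotypes(geno, file.path(out, "genotypes.tsv")),
                   write_phenotypes(pheno, file.path(out, "phenotypes.csv")),
                   write_truth_json(study, file.path(out, "truth.json")))
        pipeline_log(state, "info", sprintf(
          "simulated %d x %d genotypes (%s, h2 = %g)",
          nrow(geno), ncol(geno), arch$kind, arch$h2
        ))
      } else {
        geno <- read_genotypes(config$paths$genotypes,
                               config$paths$genotype_dialect %||% "tsv")
        pheno <- read_phenotypes(config$paths$phenotypes)
        pipeline_log(state, "info", sprintf(
          "read %d x %d genotypes and %d phenotype rows",
          nrow(geno), ncol(geno), nrow(pheno)
        ))
      }
    }
    if (is.null(geno) && any(c("qc", "adjust", "compare") %in% stages)) {
      geno <- read_genotypes(file.path(out, "genotypes.tsv"))
      pheno <- read_phenotypes(file.path(out, "phenotypes.csv"))
    }

    if ("qc" %in% stages) {
      stage_now <- "qc"
      thr <- do.call(qc_thresholds, config$qc %||% list())
      qc <- run_qc(geno, thr)
      files <- c(files, write_qc_report(qc$marker_report,
                                        file.path(out, "qc_report.csv")))
      pipeline_log(state, "info", sprintf(
        "QC kept %d/%d markers, removed %d sample(s)",
        ncol(qc$genotypes), ncol(geno), length(qc$removed_samples)
      ))
      geno <- qc$genotypes
    }

    adj <- NULL
    if ("adjust" %in% stages) {
      stage_now <- "adjust"
      adj_cfg <- config$adjust %||% list()
      adj <- adjust_phenotype(
        pheno,
        response = adj_cfg$response %||% "y",
        factors = unlist(adj_cfg$factors %||% c("sex", "birth_year")),
        covariates = unlist(adj_cfg$covariates %||%
                              c("fatten_days", "init_weight"))
      )
      yfile <- file.path(out, "adjusted_phenotypes.csv")
      data.table::fwrite(
        data.frame(id = names(adj$y_star), y_star = unname(adj$y_star),
                   stringsAsFactors = FALSE),
        yfile, quote = FALSE
      )
      files <- c(files, yfile)
      pipeline_log(state, "info",
                   sprintf("adjusted %d phenotypes", adj$n))
    }

    if ("compare" %in% stages) {
      stage_now <- "compare"
      if (is.null(adj)) {
        ys <- read_phenotypes(file.path(out, "adjusted_phenotypes.csv"))
        y_star <- setNames(ys$y_star, ys$id)
      } else {
        y_star <- adj$y_star
      }
      vcfg <- config$validation %||% list()
      plan <- if ((vcfg$scheme %||% "kfold") == "kfold") {
        kfold_split(names(y_star), k = vcfg$k %||% 5L,
                    seed = vcfg$seed %||% seed)
      } else {
        by <- setNames(pheno$birth_year, pheno$id)[names(y_star)]
        generation_split(by, vcfg$cutoff_year %||% 2013L)
      }
      methods <- config$methods %||% list(gblup = list(method = "gblup"))
      report <- run_comparison(geno, y_star, methods, plan, seed = seed)
      files <- c(files, write_accuracy_report(
        report, file.path(out, "accuracy_report.csv")
      ))
      for (nm in colnames(report$predictions)) {
        v <- report$predictions[, nm]
        v <- v[!is.na(v)]
        files <- c(files, write_gebv(v, file.path(
          out, sprintf("gebv_%s.csv", nm)
        )))
      }
      pipeline_log(state, "info", sprintf(
        "comparison done: %s",
        paste(sprintf("%s=%.3f", report$summary$method,
                      report$summary$mean_r), collapse = ", ")
      ))
    }
    0L
  }, error = function(e) {
    pipeline_log(state, "error",
                 sprintf("stage `%s` failed: %s", stage_now,
                         conditionMessage(e)))
    write_manifest(out, files, stage = stage_now,
                   status = "failed", seed = seed)
    stop(e)
  })
  write_manifest(out, files, stage = "complete", status = "ok",
                 seed = seed)
  invisible(list(files = files, report = report, status = status))
}

write_manifest <- function(out, files, stage, status, seed) {
  files <- files[file.exists(files)]
  jsonlite::write_json(list(
    package = "genopred",
    version = as.character(utils::packageVersion("genopred")),
    seed = seed,
    status = status,
    stage = stage,
    files = lapply(setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  ), file.path(out, "MANIFEST.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
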