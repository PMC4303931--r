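#' Read a table of pairwise feedback experiments
#'
#' Reads a comma-separated, UTF-8, header-required file whose column names
#' follow the experiment-record schema: `study_id`, `experiment_id`,
#' `focal_species`, `soil_species`, `control_group_id`, `hier_group_id`,
#' `mean_con`, `sd_con`, `n_con`, `mean_het`, `sd_het`, `n_het`, and the
#' moderators `life_form`, `life_cycle`, `provenance`. Unicode minus signs
#' are normalized to ASCII before numeric conversion. Rows violating the
#' record invariants are dropped with per-row diagnostics (row number and
#' reason) attached as the `"rejected"` attribute and reported via a
#' message.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing_req <- setdiff(setdiff(experiment_record_cols,
                                 c("life_form", "life_cycle", "provenance")),
                         names(raw))
  if (length(missing_req)) {
    stop("CSV is missing required columns: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("mean_con", "sd_con", "n_con", "mean_het", "sd_het", "n_het")
  for (cl in num_cols) {
    x <- gsub("−", "-", raw[[cl]])
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(val))
    if (length(bad)) {
      stop("non-numeric values in column ", cl, " (rows ",
           paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
    }
    raw[[cl]] <- val
  }
  out <- validate_records(raw, action = "filter")
  rej <- attr(out, "rejected")
  if (nrow(rej)) {
    message("read_records: dropped ", nrow(rej), " invalid row(s); see attr(",
            "x, \"rejected\") for reasons")
  }
  out
}

#' @describeIn read_records Write records back out as CSV (lossless at full
#'   double precision).
#' @param records Records tibble.
#' @export
write_records <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path)
  invisible(path)
}

#' Write a fitted model as TSV and JSON
#'
#' The TSV carries one row per term (`term`, `estimate`, `se`, `ci_lower`,
#' `ci_upper`, `n`); the JSON additionally records the model summary from
#' [glance.psf_hblm()].
#'
#' @param fit A `"psf_hblm"` object.
#' @param path Output path without extension; `.tsv` and `.json` are
#'   appended.
#' @return The two paths, invisibly.
#' @export
write_fit <- function(fit, path) {
  tab <- tidy(fit)
  tab$n <- fit$N
  readr::write_tsv(tab, paste0(path, ".tsv"))
  jsonlite::write_json(list(coefficients = tab, summary = glance(fit)),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(paste0(path, c(".tsv", ".json")))
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_pipeline()]; unknown keys
#' abort rather than being silently ignored.
#'
#' @param path Path to a YAML file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("records", "tree", "convention", "covariance_method", "rho",
             "grid_size", "tau_max", "level", "subgroups", "robustness",
             "reps", "seed", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full meta-analysis pipeline
#'
#' Orchestrates the whole analysis: read and validate the records, read the
#' chronogram, attach phylogenetic distances, assemble d/X/V, fit the
#' hierarchical and fixed models, fit the subgroup models, run the
#' robustness subsets (species trimming, distance-balanced resampling) and
#' the publication-bias diagnostics (funnel data, trim-and-fill, cumulative
#' meta-analysis). Deterministic given inputs, options and `seed`. If
#' `output_dir` is given, writes TSV/JSON results plus a plain-text run log
#' recording package versions, seed and options.
#'
#' @param records Records tibble or path to a CSV ([read_records()]).
#' @param tree `"phylo"` object or path to a Newick file
#'   ([read_chronogram()]).
#' @param convention Distance convention, see [annotate_distances()].
#' @param covariance_method Shared-control covariance formula, see
#'   [build_sampling_covariance()].
#' @param rho,grid_size,tau_max Prior settings, see [variance_prior()].
#' @param level Credible level.
#' @param subgroups Moderator columns to fit per-level models for (only
#'   those present in the records are used).
#' @param robustness Run the subset analyses and bias diagnostics?
#' @param reps,seed Replicates and seed for the distance-balanced
#'   resampling.
#' @param output_dir Optional directory for result files.
#' @return A list of class `"psf_pipeline"` with elements `records`,
#'   `dataset`, `fit`, `fit_fixed`, `subgroups`, `trim`, `resample`,
#'   `funnel`, `trimfill`, `cumulative`, and `options`.
#' @export
run_pipeline <- function(records, tree,
                         convention = c("patristic", "divergence"),
                         covariance_method = c("gleser-olkin", "simple"),
                         rho = 0.5, grid_size = 200, tau_max = NULL,
                         level = 0.95,
                         subgroups = c("life_form", "life_cycle",
                                       "provenance"),
                         robustness = TRUE, reps = 100, seed = 1,
                         output_dir = NULL) {
  convention <- match.arg(convention)
  covariance_method <- match.arg(covariance_method)
  opts <- list(convention = convention,
               covariance_method = covariance_method, rho = rho,
               grid_size = grid_size, tau_max = tau_max, level = level,
               reps = reps, seed = seed)
  prior <- variance_prior(tau_max = tau_max, grid_size = grid_size,
                          rho = rho)

  records <- stage("read_records",
                   if (is.character(records)) read_records(records) else
                     validate_records(records, action = "filter"))
  tree <- stage("read_chronogram",
                if (is.character(tree)) read_chronogram(file = tree) else
                  tree)
  records <- stage("phylo",
                   annotate_distances(records, tree,
                                      convention = convention))
  dataset <- stage("effect_sizes",
                   meta_dataset(records, method = covariance_method))
  fit <- stage("hblm", fit_hblm(dataset, prior = prior, level = level))
  fitf <- stage("hblm", fit_fixed(dataset, level = level))

  sg <- list()
  for (f in intersect(subgroups, names(records))) {
    sg[[f]] <- stage(paste0("subgroups:", f),
                     fit_subgroups(records, f, prior = prior, level = level))
  }

  trim <- resample <- funnel <- tf <- cum <- NULL
  if (robustness) {
    trim <- stage("robustness:trim",
                  trim_unique_species(records, prior = prior, level = level))
    resample <- stage("robustness:resample",
                      distance_balanced_slopes(records, reps = reps,
                                               seed = seed))
    funnel <- stage("diagnose:funnel", funnel_data(dataset$effects))
    tf <- stage("diagnose:trimfill",
                trim_and_fill(dataset$effects, level = level))
    cum <- stage("diagnose:cumulative",
                 cumulative_meta(dataset, level = level))
  }

  out <- structure(list(records = records, dataset = dataset, fit = fit,
                        fit_fixed = fitf, subgroups = sg, trim = trim,
                        resample = resample, funnel = funnel,
                        trimfill = tf, cumulative = cum, options = opts),
                   class = "psf_pipeline")
  if (!is.null(output_dir)) write_pipeline(out, output_dir)
  out
}

write_pipeline <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fit(x$fit, file.path(dir, "fit_hierarchical"))
  write_fit(x$fit_fixed, file.path(dir, "fit_fixed"))
  for (f in names(x$subgroups)) {
    readr::write_tsv(x$subgroups[[f]],
                     file.path(dir, paste0("subgroups_", f, ".tsv")))
  }
  if (!is.null(x$trim) && !is.null(x$trim$fit)) {
    write_fit(x$trim$fit, file.path(dir, "fit_trimmed"))
  }
  if (!is.null(x$resample)) {
    jsonlite::write_json(
      x$resample[c("reps", "mean_slope", "se_slope", "seed")],
      file.path(dir, "resample.json"), digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(x$funnel)) {
    readr::write_tsv(x$funnel, file.path(dir, "funnel.tsv"))
  }
  if (!is.null(x$trimfill)) {
    jsonlite::write_json(
      x$trimfill[c("k0", "side", "estimator", "adjusted_mean", "se",
                   "ci_lower", "ci_upper", "unadjusted_mean")],
      file.path(dir, "trimfill.json"), digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(x$cumulative)) {
    readr::write_tsv(tibble::as_tibble(x$cumulative),
                     file.path(dir, "cumulative.tsv"))
  }
  log <- c(
    paste0("psfmeta ", as.character(utils::packageVersion("psfmeta"))),
    paste0("R ", R.version.string),
    paste0("seed: ", x$options$seed),
    paste0("options: ", jsonlite::toJSON(x$options, auto_unbox = TRUE,
                                         null = "null")),
    paste0("N: ", x$fit$N, "  k: ", x$fit$k))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.psf_pipeline <- function(x, ...) {
  cat("<psf_pipeline> N =", x$fit$N, "effect sizes\n\nHierarchical fit:\n")
  print(x$fit)
  if (!is.null(x$trimfill)) {
    cat("\n")
    print(x$trimfill)
  }
  invisible(x)
}
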