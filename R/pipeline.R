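#' Pipeline configuration
#'
#' Bundles every choice the end-to-end pipeline needs: which stages run,
#' where outputs go, the generator truth (preset or custom), the duration
#' convention, cohort boundaries, imputation settings, stratification and a
#' single master seed from which per-stage seeds are derived by fixed
#' offsets (generate +0, impute +1, simulation +2), so any stage can be
#' rerun in isolation. Configurations round-trip through YAML/JSON
#' unchanged.
#'
#' @param out_dir output directory.
#' @param stages character vector of stages to run, in pipeline order, from
#'   `c("generate", "score", "code", "impute", "fit", "predict", "describe")`.
#' @param preset model/truth preset name (see [model_preset()]).
#' @param n_individuals panel size for the generate stage.
#' @param duration_convention `"diagnosis_year"` or `"first_report"`.
#' @param cohort_boundary_set `"table"` or `"alternative"`.
#' @param impute_m number of imputations (0 disables imputation even if the
#'   stage is listed).
#' @param stratify fit male/female strata in addition to the pooled model.
#' @param master_seed master RNG seed.
#' @param panel_path optional path to an external panel CSV used instead of
#'   the generate stage.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "pipeline_out",
                            stages = c("generate", "score", "code", "fit",
                                       "predict", "describe"),
                            preset = "model1",
                            n_individuals = 2000,
                            duration_convention = "diagnosis_year",
                            cohort_boundary_set = "table",
                            impute_m = 0,
                            stratify = FALSE,
                            master_seed = 1L,
                            panel_path = NULL) {
  cfg <- list(out_dir = out_dir, stages = stages, preset = preset,
              n_individuals = n_individuals,
              duration_convention = duration_convention,
              cohort_boundary_set = cohort_boundary_set,
              impute_m = impute_m, stratify = stratify,
              master_seed = as.integer(master_seed),
              panel_path = panel_path)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  known <- c("generate", "score", "code", "impute", "fit", "predict", "describe")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "))
  if (!cfg$preset %in% c("model1", "model2", "model3", "male", "female"))
    stop("unknown preset name: ", cfg$preset)
  if (!cfg$duration_convention %in% c("diagnosis_year", "first_report"))
    stop("unknown duration convention: ", cfg$duration_convention)
  if (!cfg$cohort_boundary_set %in% c("table", "alternative"))
    stop("unknown cohort boundary set: ", cfg$cohort_boundary_set)
  if (cfg$impute_m < 0) stop("impute_m must be >= 0")
  invisible(cfg)
}

#' Read / write a pipeline configuration
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param cfg a `pipeline_config`.
#' @return `read_pipeline_config()` returns a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  raw$stages <- as.character(raw$stages)
  if (!is.null(raw$panel_path) && !nzchar(raw$panel_path)) raw$panel_path <- NULL
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$panel_path <- if (is.null(x$panel_path)) "" else x$panel_path
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order — generate (or load), score, code,
#' impute, fit, predict, describe — writing every intermediate table as
#' CSV and returning a manifest (package version, seeds, conventions,
#' output checksums). Identical configurations produce identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the run manifest (list), invisibly written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[dalytraj] ", ...)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  seeds <- list(generate = cfg$master_seed,
                impute = cfg$master_seed + 1L,
                simulate = cfg$master_seed + 2L)
  panel <- coded <- fit <- NULL
  breaks <- cohort_breaks(cfg$cohort_boundary_set)

  if ("generate" %in% cfg$stages || is.null(cfg$panel_path)) {
    say("generate: n = ", cfg$n_individuals)
    tc <- truth_config(n_individuals = cfg$n_individuals,
                       preset = cfg$preset, seed = seeds$generate)
    panel <- generate_panel(tc)
    emit(panel, "panel.csv")
  } else {
    say("loading external panel from ", cfg$panel_path)
    panel <- read.csv(cfg$panel_path, stringsAsFactors = FALSE)
  }

  if ("score" %in% cfg$stages) {
    say("score: duration convention = ", cfg$duration_convention)
    scored <- score_panel(panel, convention = cfg$duration_convention)
    panel$dalys <- scored$dalys
    emit(scored, "scored.csv")
  }

  if ("code" %in% cfg$stages) {
    say("code: cohort boundaries = ", cfg$cohort_boundary_set)
    coded <- code_panel(panel, breaks = breaks)
    emit(coded, "coded.csv")
    jsonlite::write_json(attr(coded, "codebook"),
                         file.path(cfg$out_dir, "codebook.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    outputs <- c(outputs, file.path(cfg$out_dir, "codebook.json"))
  }

  completed <- NULL
  if ("impute" %in% cfg$stages && cfg$impute_m > 0 && !is.null(coded)) {
    say("impute: m = ", cfg$impute_m)
    completed <- impute_missing(coded, m = cfg$impute_m, seed = seeds$impute)
  }

  if ("fit" %in% cfg$stages && !is.null(coded)) {
    spec <- spec_from_preset(cfg$preset)
    say("fit: preset ", cfg$preset, ", ", spec$estimation)
    if (!is.null(completed)) {
      fits <- lapply(completed, fit_growth, spec = spec, se_random = FALSE)
      pooled <- pool_fits(fits)
      emit(pooled, "fit_pooled.csv")
      fit <- fits[[1]]
    } else {
      fit <- fit_growth(coded, spec)
    }
    write_fit_csv(fit, file.path(cfg$out_dir, "fit.csv"))
    outputs <- c(outputs, file.path(cfg$out_dir, "fit.csv"))
    if (cfg$stratify) {
      for (s in c("male", "female")) {
        sf <- stratified_fit(coded, spec, s, se_random = FALSE)
        write_fit_csv(sf, file.path(cfg$out_dir, paste0("fit_", s, ".csv")))
        outputs <- c(outputs, file.path(cfg$out_dir, paste0("fit_", s, ".csv")))
      }
    }
  }

  if ("predict" %in% cfg$stages && !is.null(fit) && !is.null(coded)) {
    say("predict: cohort trajectory grid")
    meds <- unlist(attr(coded, "codebook")$age_centering$cohort_medians)
    profiles <- reference_profiles(fit, coded)
    grid <- predict_trajectories(fit, profiles, cohort_medians = meds)
    emit(grid, "trajectories.csv")
  }

  if ("describe" %in% cfg$stages && !is.null(coded) && "dalys" %in% names(coded)) {
    say("describe: per-cohort summary")
    emit(descriptive_table(coded), "descriptives.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dalytraj")),
    r_version = R.version.string,
    config = unclass(cfg),
    seeds = seeds,
    conventions = list(duration = cfg$duration_convention,
                       cohort_boundaries = as.integer(breaks),
                       income_log_base = 10,
                       median = "lower"),
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Reference covariate profiles for trajectory plots
#'
#' One profile per cohort: dummy controls at their reference category (0),
#' continuous controls at the sample mean, cohort at its own value. The
#' policy is recorded so figures are reproducible.
#'
#' @param fit a `growth_fit`.
#' @param coded the coded panel the fit used.
#' @return data frame of profiles with `label` and `cohort` columns.
#' @export
reference_profiles <- function(fit, coded) {
  terms <- fit$fixed_effects$term
  vars <- setdiff(unique(unlist(strsplit(terms, ":", fixed = TRUE))),
                  c("(Intercept)", "age_c", "age_c2", "cohort"))
  prof <- lapply(vars, function(v) {
    x <- coded[[v]]
    if (all(x %in% c(0, 1))) 0 else mean(x, na.rm = TRUE)
  })
  names(prof) <- vars
  out <- do.call(rbind, lapply(1:4, function(co)
    data.frame(label = paste0("cohort", co), cohort = co,
               as.data.frame(prof), check.names = FALSE)))
  out
}
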