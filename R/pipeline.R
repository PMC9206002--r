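#' Derive a stage seed from a master seed
#'
#' Deterministic derivation `(master * 48271 + weighted character sum of the
#' stage name) mod (2^31 - 1)`: every pipeline stage gets its own
#' reproducible stream without seed collisions between stages.
#'
#' @param master Integer master seed.
#' @param stage Stage name (any string).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch))
  as.integer(1 + (as.numeric(master) * 48271 + h) %% 2147483645)
}

#' Assemble a pipeline configuration
#'
#' @param cohort Named list of [cohort_spec()] arguments (the master seed
#'   overrides its `seed`).
#' @param models Models to fit (default all four).
#' @param n_restarts Restarts per subject fit.
#' @param comparisons Named list of model subsets to compare; defaults to the
#'   two presets `base` (M1-M3) and `full` (M1-M4).
#' @param n_mc Dirichlet Monte-Carlo samples for the exceedance
#'   probabilities.
#' @param seed Master seed; all stage seeds derive from it via
#'   [stage_seed()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = list(), models = c("M1", "M2", "M3", "M4"),
                            n_restarts = 10,
                            comparisons = list(base = c("M1", "M2", "M3"),
                                               full = c("M1", "M2", "M3", "M4")),
                            n_mc = 1e6, seed = 1) {
  models <- match.arg(models, .model_ids, several.ok = TRUE)
  for (cmp in comparisons) stopifnot(all(cmp %in% models))
  structure(list(cohort = cohort, models = models, n_restarts = n_restarts,
                 comparisons = comparisons, n_mc = n_mc, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("cohort", "models", "n_restarts", "comparisons", "n_mc", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(args$models)) args$models <- as.character(args$models)
  if (!is.null(args$comparisons)) {
    args$comparisons <- lapply(args$comparisons, as.character)
  }
  do.call(pipeline_config, args)
}

#' Run the full synthetic-study pipeline
#'
#' One call reproduces the whole analysis on synthetic data: generate a
#' cohort, fit the requested models to every subject, run random-effects
#' model selection for each comparison preset, test the drug contrast on the
#' fitted parameters, and summarise drug-effect recovery. All outputs are
#' written under `out_dir` (CSV tables, JSON reports, and a `manifest.json`
#' recording derived seeds and per-stage status); numeric outputs are
#' byte-identical across runs with the same configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(cohort = stage_seed(config$seed, "cohort"),
                fit = stage_seed(config$seed, "fit"),
                bms = stage_seed(config$seed, "bms"))
  manifest <- list(package_version = as.character(utils::packageVersion("mgng")),
                   master_seed = config$seed, stage_seeds = seeds,
                   config = unclass(config), stages = list())
  done <- function(stage, status, files = character(0)) {
    manifest$stages[[stage]] <<- list(status = status, files = files)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      done(stage, paste("failed:", conditionMessage(e)))
      NULL
    })
  }

  # --- cohort ---------------------------------------------------------
  cohort <- run_stage("cohort", {
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = seeds$cohort)))
    co <- generate_cohort(spec)
    write_trials(co$data, file.path(out_dir, "cohort.csv"))
    write.csv(as.data.frame(co$params), file.path(out_dir, "true_params.csv"),
              row.names = FALSE)
    done("cohort", "ok", c("cohort.csv", "true_params.csv"))
    c(co, list(spec = spec))
  })

  # --- fits -----------------------------------------------------------
  fits <- if (!is.null(cohort)) run_stage("fit", {
    cf <- fit_cohort(cohort$data, models = config$models,
                     n_restarts = config$n_restarts, seed = seeds$fit)
    write.csv(as.data.frame(fits_table(cf)), file.path(out_dir, "fits.csv"),
              row.names = FALSE)
    done("fit", "ok", "fits.csv")
    cf
  }) else { done("fit", "skipped"); NULL }

  # --- model comparison ------------------------------------------------
  if (!is.null(fits)) run_stage("bms", {
    L <- evidence_matrix(fits)
    files <- character(0)
    for (nm in names(config$comparisons)) {
      bms <- run_bms(L[, config$comparisons[[nm]], drop = FALSE],
                     n_mc = config$n_mc,
                     seed = stage_seed(seeds$bms, nm))
      f <- paste0("bms_", nm, ".csv")
      write.csv(as.data.frame(frequency_report(bms)), file.path(out_dir, f),
                row.names = FALSE)
      files <- c(files, f)
    }
    done("bms", "ok", files)
  }) else done("bms", "skipped")

  # --- drug contrast ----------------------------------------------------
  if (!is.null(fits) && "M4" %in% config$models) run_stage("contrast", {
    ct <- drug_contrast(fits)
    write.csv(as.data.frame(ct), file.path(out_dir, "contrast.csv"),
              row.names = FALSE)
    done("contrast", "ok", "contrast.csv")
  }) else done("contrast", "skipped")

  # --- recovery ---------------------------------------------------------
  if (!is.null(fits) && !is.null(cohort) && "M4" %in% config$models) {
    run_stage("recovery", {
      tab <- fits_table(fits)
      rep <- recovery_report(cohort$params, tab[tab$model_id == "M4", ],
                             cohort$spec$drug_effect_pi)
      jsonlite::write_json(
        list(pi_shift = rep$pi_shift, p_value = rep$p_value,
             statistic = rep$statistic, sign_agrees = rep$sign_agrees,
             n_subjects = rep$n_subjects,
             correlations = as.data.frame(rep$correlations)),
        file.path(out_dir, "recovery.json"), auto_unbox = TRUE, digits = NA)
      done("recovery", "ok", "recovery.json")
    })
  } else done("recovery", "skipped")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
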