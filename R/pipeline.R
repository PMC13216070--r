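## End-to-end pipeline over the synthetic world:
## simulate -> ingest -> fit -> predict -> report, each stage resumable from
## its on-disk artifacts. The pipeline is the package's reproducibility
## harness; analyses of real survey tables call the stage functions directly.

# default submodel formulas matching the generative structure of the
# synthetic world (region-varying intercepts and slopes, V3 factor)
sim_formulas <- function() {
  list(consumption = ~ 0 + region + region:V1 + v3,
       frequency = ~ 0 + region + region:V2 + v3,
       quantity = ~ 0 + region + region:V2)
}

#' Configuration for [run_pipeline()]
#'
#' @param out output directory for stage artifacts.
#' @param seed integer seed governing every stage.
#' @param stages subset of `c("simulate", "ingest", "fit", "predict",
#'   "report")` to execute; skipped stages are loaded from `out`.
#' @param spec landscape specification, see [landscape_spec()].
#' @param obs observation specification, see [observation_spec()].
#' @param formulas submodel formulas (defaults match the synthetic world).
#' @param spatial submodels carrying a spatial term.
#' @param chains,iterations,warmup sampler settings.
#' @param priors prior overrides passed to [default_priors()].
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(out, seed = 1,
                            stages = c("simulate", "ingest", "fit",
                                       "predict", "report"),
                            spec = landscape_spec(),
                            obs = observation_spec(),
                            formulas = sim_formulas(),
                            spatial = "consumption",
                            chains = 1, iterations = 1500, warmup = 1000,
                            priors = list()) {
  list(out = out, seed = seed, stages = stages, spec = spec, obs = obs,
       formulas = formulas, spatial = spatial, chains = chains,
       iterations = iterations, warmup = warmup, priors = priors)
}

#' Run the simulate / ingest / fit / predict / report pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' under `config$out` (`data/` CSV tables and ground truth, `draws.csv` and
#' `diagnostics.json`, `cells_prediction.csv`, `regional_summary.json`,
#' `provenance.json`). A stage absent from `config$stages` is resumed from
#' its artifacts; a missing input raises an error naming the stage without
#' writing partial outputs.
#'
#' @param config list from [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return invisibly, a list with the in-memory objects of the executed or
#'   loaded stages (`world`, `survey`, `fit`, `prediction`, `summary`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  has <- function(stage) stage %in% config$stages
  data_dir <- file.path(out, "data")

  ## --- simulate ---------------------------------------------------------
  world <- NULL
  if (has("simulate")) {
    say("simulate: coverage ", config$obs$coverage, ", seed ", config$seed)
    world <- synthetic_survey(config$spec, config$obs, config$seed)
    write_survey(world$survey, data_dir)
    cells <- world$truth$cells
    utils::write.csv(cells, file.path(data_dir, "cells.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(world$truth$summary,
        list(params = world$truth$params[c("a0", "a1", "a2", "b0", "b1",
                                           "b2", "g0", "g1", "g2", "theta",
                                           "zeta", "rho", "sigma")])),
      file.path(data_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    say("simulate: ", nrow(world$survey$locations), " locations, ",
        nrow(world$survey$households), " households, ",
        nrow(world$survey$recalls), " recalls")
  }

  ## --- ingest -----------------------------------------------------------
  survey <- if (!is.null(world)) world$survey else NULL
  if (has("ingest") || (is.null(survey) && any(has(c("fit", "predict"))))) {
    if (!file.exists(file.path(data_dir, "recalls.csv")))
      stop("survey tables missing under ", data_dir,
           " (run or resume the simulate stage first)")
    survey <- read_survey(data_dir)
    # CSV round-trips drop factor types of the simulation covariates
    if ("region" %in% names(survey$locations))
      survey$locations$region <- factor(survey$locations$region)
    if ("v3" %in% names(survey$households))
      survey$households$v3 <- factor(survey$households$v3,
                                     levels = c("a", "b"))
    say("ingest: ", nrow(survey$recalls), " recalls kept, ",
        length(survey$report$exclusions), " exclusion rule(s) triggered")
  }

  ## --- fit --------------------------------------------------------------
  fit <- NULL
  mdata <- NULL
  build_mdata <- function() prepare_model_data(
    survey, consumption = config$formulas$consumption,
    frequency = config$formulas$frequency,
    quantity = config$formulas$quantity, spatial = config$spatial)
  if (has("fit")) {
    mdata <- build_mdata()
    priors <- do.call(default_priors, c(list(mdata), config$priors))
    say("fit: ", config$chains, " chain(s) x ", config$iterations,
        " iterations (", mdata$n_clamped, " clamped frequencies, ",
        mdata$n_miss_ame, " AMEs to impute)")
    fit <- sample_posterior(mdata, chains = config$chains,
                            iterations = config$iterations,
                            warmup = config$warmup, seed = config$seed,
                            priors = priors)
    utils::write.csv(as.data.frame(fit$draws),
                     file.path(out, "draws.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(rhat = as.list(round(fit$rhat, 4)),
           acceptance = as.list(round(fit$acceptance, 3)),
           clamped = fit$n_clamped),
      file.path(out, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
    say("fit: max Rhat ", round(max(fit$rhat, na.rm = TRUE), 3))
  } else if (any(has(c("predict", "report")))) {
    if (!file.exists(file.path(out, "draws.csv")))
      stop("predict stage: no cached draws.csv under ", out)
    mdata <- build_mdata()
    draws <- as.matrix(utils::read.csv(file.path(out, "draws.csv"),
                                       check.names = FALSE))
    fit <- structure(list(draws = draws, mdata = mdata,
                          rhat = rep(NA_real_, ncol(draws))),
                     class = "wm_fit")
  }

  ## --- predict ----------------------------------------------------------
  prediction <- NULL
  if (has("predict")) {
    cf <- file.path(data_dir, "cells.csv")
    if (!file.exists(cf)) stop("predict stage: no cells.csv under ", data_dir)
    cells <- utils::read.csv(cf)
    cells$region <- factor(cells$region)
    cells$ame <- cells$ame_total
    w <- list(v3 = stats::setNames(config$spec$v3_level_probs, c("a", "b")))
    design <- list(
      consumption = build_cell_design(config$formulas$consumption, cells, w,
                                      fit$mdata$cons$xlevels),
      frequency = build_cell_design(config$formulas$frequency, cells, w,
                                    fit$mdata$freq$xlevels),
      quantity = build_cell_design(config$formulas$quantity, cells,
                                   xlevels = fit$mdata$quant$xlevels))
    prediction <- predict_cells(fit, cells, design, seed = config$seed)
    utils::write.csv(prediction$summary,
                     file.path(out, "cells_prediction.csv"),
                     row.names = FALSE)
    say("predict: ", nrow(cells), " cells, median total ",
        round(stats::median(prediction$total_tonnes), 1), " t/year")
  }

  ## --- report -----------------------------------------------------------
  summary_out <- NULL
  if (has("report")) {
    if (is.null(prediction)) {
      pf <- file.path(out, "cells_prediction.csv")
      if (!file.exists(pf)) stop("report stage: no prediction artifacts")
    }
    tt <- prediction$total_tonnes
    summary_out <- list(
      total_tonnes = list(median = stats::median(tt), mean = mean(tt),
                          sd = stats::sd(tt),
                          q025 = unname(stats::quantile(tt, 0.025)),
                          q975 = unname(stats::quantile(tt, 0.975))),
      n_cells = nrow(prediction$summary),
      seed = config$seed)
    jsonlite::write_json(summary_out,
                         file.path(out, "regional_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_file <- file.path(out, "config.json")
    cfg_json <- jsonlite::toJSON(config[c("seed", "stages", "spatial",
                                          "chains", "iterations", "warmup")],
                                 auto_unbox = TRUE)
    writeLines(cfg_json, cfg_file)
    jsonlite::write_json(
      list(config_hash = unname(tools::md5sum(cfg_file)),
           seed = config$seed,
           package_version = as.character(utils::packageVersion("wildmeatr")),
           r_version = R.version.string),
      file.path(out, "provenance.json"), auto_unbox = TRUE)
    say("report: written to ", out)
  }

  invisible(list(world = world, survey = survey, fit = fit,
                 prediction = prediction, summary = summary_out))
}

#' Packaged synthetic test datasets
#'
#' `tiny` is a 100-cell landscape observed at 20 locations with roughly 200
#' households (runs in seconds end to end); `small` is the default 900-cell
#' landscape at the 10% coverage scenario (90 locations). Both are generated
#' in code, byte-stable for a fixed seed.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed integer seed.
#' @return as [synthetic_survey()]: list with `survey`, `truth` and the
#'   surveyed-cell bookkeeping.
#' @export
make_fixtures <- function(size = c("tiny", "small"), seed = 1) {
  size <- match.arg(size)
  if (size == "tiny") {
    spec <- landscape_spec(n_cells = 100, region_sizes = c(40, 20, 40),
                           household_count_means = c(20, 50, 33))
    obs <- observation_spec(coverage = 0.20,
                            household_sampling_fraction = 0.30)
  } else {
    spec <- landscape_spec()
    obs <- observation_spec(coverage = 0.10)
  }
  synthetic_survey(spec, obs, seed)
}
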