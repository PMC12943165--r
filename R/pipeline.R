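#' Assemble a pipeline configuration
#'
#' Collects every setting of the end-to-end QSAR workflow: data source
#' (a descriptor CSV or a synthetic preset), pre-filter thresholds, split
#' settings, GA configuration, validation settings, and the output
#' directory. One master `seed` propagates to every stochastic stage
#' unless the stage is given its own.
#'
#' @param input Path to a descriptor CSV, or `NULL` to simulate.
#' @param preset `"study57"` or `"study_pool"` (used when `input` is
#'   `NULL`).
#' @param activity Activity column name.
#' @param external_count External-set size for [make_split()].
#' @param split_strategy `"sorted_stride"` or `"random"`.
#' @param max_modal_fraction,r_threshold Pre-filter thresholds.
#' @param ga A [ga_config()]; its seed is overridden by `seed`.
#' @param n_permutations,lmo_repeats,lmo_group_size Validation settings.
#' @param out_dir Output directory for the report bundle.
#' @param seed Master integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, preset = "study57",
                            activity = "pIC50", external_count = 10,
                            split_strategy = "sorted_stride",
                            max_modal_fraction = 0.80, r_threshold = 0.95,
                            ga = ga_config(),
                            n_permutations = 100, lmo_repeats = 50,
                            lmo_group_size = NULL,
                            out_dir = tempfile("qsardyn_run_"),
                            seed = 1L) {
  if (!is.null(input) && !file.exists(input)) {
    abort(paste0("input file not found: ", input), class = "qsardyn_io")
  }
  stopifnot(inherits(ga, "ga_config"))
  ga$seed <- as.integer(seed)
  structure(list(input = input, preset = preset, activity = activity,
                 external_count = external_count,
                 split_strategy = split_strategy,
                 max_modal_fraction = max_modal_fraction,
                 r_threshold = r_threshold, ga = ga,
                 n_permutations = n_permutations,
                 lmo_repeats = lmo_repeats,
                 lmo_group_size = lmo_group_size,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end QSAR pipeline
#'
#' Executes ingest/simulate, two-stage pre-filter, train/external split,
#' GA-MLR descriptor selection, the full validation battery,
#' applicability-domain analysis, and external prediction, writing a
#' report bundle (`prefilter.json`, `split.csv`, `model.json`,
#' `ga_trace.csv`, `validation.json`, `validation.csv`, `ad.csv`,
#' `predictions.csv`, `manifest.json`) into the configured output
#' directory. The manifest records the package version, every seed and
#' every default in effect, so a run is reproducible from it.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted `ga` result, the
#'   `validation` report, the `ad` report, the `split`, the pre-filter
#'   report and `out_dir`. Stage failures propagate as errors naming the
#'   stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "qsardyn_stage_error", parent = e)
    })
  }
  inform("stage: ingest")
  data <- stage("ingest", {
    if (!is.null(config$input)) {
      read_descriptor_table(config$input, activity_column = config$activity)
    } else {
      spec <- switch(config$preset,
                     study57 = preset_study57(seed = config$seed),
                     study_pool = preset_study_pool(seed = config$seed),
                     abort(paste0("unknown preset '", config$preset, "'")))
      gen_qsar_dataset(spec)$data
    }
  })
  inform("stage: prefilter")
  filtered <- stage("prefilter", prefilter(
    data, max_modal_fraction = config$max_modal_fraction,
    r_threshold = config$r_threshold, activity = config$activity))
  write_prefilter_report(prefilter_report(filtered),
                         file.path(config$out_dir, "prefilter.json"))
  inform("stage: split")
  split <- stage("split", make_split(
    filtered, external_count = config$external_count,
    strategy = config$split_strategy, activity = config$activity,
    seed = config$seed))
  write_split(split, file.path(config$out_dir, "split.csv"))
  ids <- dt_parts(filtered, activity = config$activity)$ids
  train <- filtered[ids %in% split$compound_id[split$partition == "train"], ]
  external <- filtered[ids %in% split$compound_id[split$partition == "external"], ]
  inform("stage: ga_select")
  ga <- stage("ga_select", ga_select(train, config$activity, config$ga))
  if (ga$all_rejected) {
    abort("GA found no subset passing the QUIK rule; relax quik_delta",
          class = "qsardyn_all_rejected")
  }
  write_ga_trace(ga, file.path(config$out_dir, "ga_trace.csv"))
  write_model_spec(ga$fit$model, file.path(config$out_dir, "model.json"))
  inform("stage: validate")
  report <- stage("validate", validate_model(
    filtered, config$activity, ga$descriptors, split = split,
    n_permutations = config$n_permutations,
    lmo_group_size = config$lmo_group_size,
    lmo_repeats = config$lmo_repeats, seed = config$seed))
  write_validation_report(report, file.path(config$out_dir, "validation.json"))
  write_validation_report(report, file.path(config$out_dir, "validation.csv"))
  inform("stage: applicability_domain")
  ad <- stage("applicability_domain", applicability_domain(
    report$fit, newdata = if (nrow(external)) external else NULL,
    activity = config$activity))
  write_ad_report(ad, file.path(config$out_dir, "ad.csv"))
  inform("stage: predict")
  preds <- stage("predict", {
    newdata <- if (nrow(external)) external else train
    tibble(compound_id = dt_parts(newdata, activity = config$activity)$ids,
           predicted = predict_pic50(ga$fit$model, newdata,
                                     .warn_extra = FALSE))
  })
  readr::write_csv(preds, file.path(config$out_dir, "predictions.csv"),
                   progress = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("qsardyn")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), c("ga", "out_dir"))],
    ga_config = unclass(config$ga),
    selected_descriptors = ga$descriptors,
    metrics = as.list(report$metrics)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(data = filtered, split = split, ga = ga,
                 validation = report, ad = ad,
                 prefilter = prefilter_report(filtered),
                 out_dir = config$out_dir))
}
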