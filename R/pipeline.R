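# End-to-end pipeline: premodel -> fit -> evaluate (-> recovery), with a
# reproducible artifact manifest. The stages are ordinary package functions;
# this wrapper ties them together for scripted runs.

#' Build a pipeline configuration
#'
#' @param input path to a trial-level DOR CSV, or `NULL` to simulate a
#'   dataset from a planted BU model.
#' @param models model names to fit and compare.
#' @param scheme evaluation scheme, `"kfold"` or `"individual"`.
#' @param restarts restarts per fit.
#' @param repetitions recovery repetitions (0 skips the recovery stage).
#' @param seed integer seed recorded in every artifact.
#' @param outdir output directory.
#' @param preset `"paper"` (100 restarts, 100 repetitions) or `"ci"`
#'   (5 restarts, 5 repetitions, reduced model set) scale preset; explicit
#'   `restarts`/`repetitions`/`models` values override the preset.
#' @return a named list of class `run_config`.
#' @export
pipeline_config <- function(input = NULL, models = NULL, scheme = "kfold",
                            restarts = NULL, repetitions = NULL, seed = 1L,
                            outdir = "chordexpect-run",
                            preset = c("ci", "paper")) {
  preset <- match.arg(preset)
  defaults <- if (preset == "paper") {
    list(restarts = 100L, repetitions = 100L, models = MODEL_NAMES)
  } else {
    list(restarts = 5L, repetitions = 5L, models = c("1P", "1M", "BU"))
  }
  cfg <- list(input = input,
              models = models %||% defaults$models,
              scheme = scheme,
              restarts = as.integer(restarts %||% defaults$restarts),
              repetitions = as.integer(repetitions %||% defaults$repetitions),
              seed = as.integer(seed),
              outdir = outdir,
              preset = preset)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose fields mirror the
#'   arguments of [pipeline_config()].
#' @return a `run_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the rating data, pre-modelling
#' statistics, per-model fits with the configured scheme, pairwise model
#' comparison, and (when `repetitions > 0`) a parameter-recovery study for
#' the first configured model. Every output file is listed in a manifest
#' with its MD5 hash, the seed, and a hash of the configuration, so a run
#' is reproducible from (config, seed) alone.
#'
#' @param config a `run_config` (see [pipeline_config()]).
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json` in `config$outdir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$input) && !file.exists(config$input)) {
    stop("input file not found: ", config$input, call. = FALSE)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(config$outdir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  # -- data ----------------------------------------------------------------
  if (is.null(config$input)) {
    planted <- sample_params("BU", seed = config$seed)
    dataset <- simulate_experiment(planted, participants = 5L, noise_sd = 1,
                                   seed = config$seed)
  } else {
    dataset <- read_dor_csv(config$input)
  }

  # -- premodel ------------------------------------------------------------
  tab2 <- average_dors(dataset, 2L)
  kw <- lapply(c("interval", "first_pitch", "second_pitch"), function(f) {
    r <- kruskal_wallis_by_factor(tab2, f)
    data.frame(test = r$test_name, statistic = r$statistic, df = r$df,
               p = r$p)
  })
  tab3 <- average_dors(dataset, 3L)
  fr <- lapply(c("interval_from_first", "interval_from_second"), function(tr) {
    r <- friedman_by_interval(tab3, tr)
    data.frame(test = r$test_name, statistic = r$statistic, df = r$df,
               p = r$p)
  })
  emit_csv(do.call(rbind, c(kw, fr)), "premodel_tests.csv")
  prof <- interval_profile_vectors(dataset)
  emit_csv(data.frame(position = rownames(prof), prof, check.names = FALSE),
           "interval_profiles.csv")
  mds <- nonmetric_mds(dist(prof), dims = 2L, nstarts = 20L,
                       seed = config$seed)
  emit_csv(data.frame(position = rownames(prof), mds$coordinates,
                      stress = mds$stress), "profile_mds.csv")

  # -- fit & evaluate ------------------------------------------------------
  cmp <- model_comparison(dataset, models = config$models,
                          scheme = config$scheme,
                          restarts = config$restarts, seed = config$seed)
  emit_csv(cmp$table, "model_comparison.csv")
  emit_csv(data.frame(unit = rownames(cmp$test_H), cmp$test_H,
                      check.names = FALSE), "test_cross_entropies.csv")
  for (m in config$models) {
    best_unit <- which.min(cmp$test_H[, m])
    path <- file.path(config$outdir, sprintf("params_%s.json", m))
    write_params_json(cmp$fits[[best_unit]][[m]]$params, path)
    files <- c(files, path)
  }

  # -- recovery ------------------------------------------------------------
  if (config$repetitions > 0) {
    rec <- recovery_study(config$models[1], repetitions = config$repetitions,
                          restarts = config$restarts, seed = config$seed)
    emit_csv(data.frame(parameter = names(rec$bias), bias = rec$bias,
                        sd = rec$sd), "recovery.csv")
  }

  # -- manifest ------------------------------------------------------------
  cfg_plain <- unclass(config)
  manifest <- list(
    seed = config$seed,
    config = cfg_plain,
    config_hash = unname(.hash_object(cfg_plain)),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

.hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                              null = "null"), tmp)
  tools::md5sum(tmp)
}
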