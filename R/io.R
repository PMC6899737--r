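# CSV readers with schema validation, pipeline configuration, and the
# stage orchestrator.  All artifacts are plain CSV/JSON.

#' Read and validate feeding-trial records
#'
#' Expected columns: `dataset_id`, `predator_present` (0/1 or logical),
#' `temperature_C`, `n0`, `n_survivors`, and optionally `duration_days`
#' (default 1), `predator_species` and `excluded` (excluded rows are
#' dropped with a message).  Validation failures name the offending row.
#'
#' @param path CSV file path.
#' @return Validated data.frame of trials.
#' @export
read_trials <- function(path) {
  validate_trials(read.csv(path, stringsAsFactors = FALSE))
}

#' Read and validate respirometry records
#'
#' Expected columns: `temperature_C`, `o2_umol_per_h`, and optionally
#' `species` and `dry_mass_mg`.
#'
#' @param path CSV file path.
#' @return Validated data.frame of respirometry records.
#' @export
read_respirometry <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("temperature_C", "o2_umol_per_h")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    stop("respirometry records missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(rec$o2_umol_per_h < 0)
  if (length(bad))
    stop("negative O2 rate in row(s): ", paste(bad, collapse = ", "))
  rec
}

#' Read and validate stream-survey records
#'
#' Expected columns: `stream_id`, `mean_temp_C`, `simuliidae_abundance`,
#' and optionally `predator_species`, `predator_abundance`.
#'
#' @param path CSV file path.
#' @return Validated data.frame of stream records.
#' @export
read_streams <- function(path) {
  st <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("stream_id", "mean_temp_C", "simuliidae_abundance")
  miss <- setdiff(req, names(st))
  if (length(miss))
    stop("stream records missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(st$simuliidae_abundance < 0)
  if (length(bad))
    stop("negative prey abundance in row(s): ", paste(bad, collapse = ", "))
  st
}

#' Pipeline configuration
#'
#' All tunables of the analysis chain in one serializable list: the
#' constants block, solver and optimizer settings, prey energetics,
#' per-species mass defaults, the field-rate multiplier and the
#' arena/area density scaling.  A run's configuration is echoed as JSON
#' into its output directory.
#'
#' @param constants [fr_constants()].
#' @param assimilation [assimilation_params()].
#' @param prey [prey_energetics()].
#' @param control [fr_control()].
#' @param predator_mass_mg Dry mass for metabolic prediction (NULL: mean
#'   respirometry mass).
#' @param field_rate_multiplier Routine-to-field metabolic multiplier.
#' @param area_scaling Survey-to-arena density scaling.
#' @param seed Base RNG seed.
#' @param zoo_subset Optional row indices of [fr_model_zoo()] to restrict
#'   the candidate set (for fast runs); NULL fits all 55.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(constants = fr_constants(),
                            assimilation = assimilation_params(),
                            prey = prey_energetics(),
                            control = fr_control(),
                            predator_mass_mg = NULL,
                            field_rate_multiplier = 1,
                            area_scaling = 1,
                            seed = 1,
                            zoo_subset = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis chain
#'
#' Stages, in order: fit natural mortality from controls; fit the
#' functional-response model zoo and select by BIC; fit the metabolic
#' scaling models; compute per-stream energetic efficiency and its
#' smoothers.  Writes all fits, the full BIC tables (not just winners),
#' the efficiency table and a JSON echo of the configuration to `out_dir`.
#'
#' @param trials Feeding-trial data.frame (or CSV path).
#' @param respirometry Respirometry data.frame (or CSV path).
#' @param streams Stream-survey data.frame (or CSV path), or NULL to skip
#'   the energetics stage.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param field_dataset Dataset label whose attack coefficient drives the
#'   field feeding prediction.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the fitted objects and the efficiency
#'   table.
#' @export
run_pipeline <- function(trials, respirometry, streams = NULL,
                         out_dir = tempfile("thermofr_run_"),
                         config = pipeline_config(),
                         field_dataset = "Field2015",
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  if (is.character(trials)) trials <- read_trials(trials)
  else trials <- validate_trials(trials)
  if (is.character(respirometry))
    respirometry <- read_respirometry(respirometry)
  if (!is.null(streams) && is.character(streams))
    streams <- read_streams(streams)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE, null = "null")
  writeLines(cfg_json, file.path(out_dir, "config.json"))
  cfg_hash <- sum(utf8ToInt(as.character(cfg_json))) %% 1e9

  say("stage 1/4: natural mortality")
  mort <- fit_mortality(trials, config$constants)
  write.csv(cbind(config_hash = cfg_hash, mort$selected),
            file.path(out_dir, "mortality_fits.csv"), row.names = FALSE)

  say("stage 2/4: functional-response zoo")
  datasets <- sort(unique(trials$dataset_id[trials$predator_present]))
  specs <- fr_model_zoo(length(datasets))
  if (!is.null(config$zoo_subset))
    specs <- specs[config$zoo_subset, , drop = FALSE]
  zoo <- fit_fr_zoo(trials, mortality = mort, specs = specs,
                    constants = config$constants, control = config$control,
                    verbose = FALSE)
  write.csv(cbind(config_hash = cfg_hash, zoo$bic_table),
            file.path(out_dir, "fr_bic_table.csv"), row.names = FALSE)
  win_sum <- summary(zoo$winner)
  write.csv(cbind(config_hash = cfg_hash, win_sum$table),
            file.path(out_dir, "fr_winner_params.csv"), row.names = FALSE)

  say("stage 3/4: metabolic scaling")
  met <- fit_metabolism(respirometry, config$constants)
  met_sum <- summary(met)
  write.csv(cbind(config_hash = cfg_hash, met_sum$table),
            file.path(out_dir, "metabolic_winner_params.csv"),
            row.names = FALSE)
  write.csv(cbind(config_hash = cfg_hash, met$ranking),
            file.path(out_dir, "metabolic_bic_table.csv"), row.names = FALSE)

  eff <- profiles <- NULL
  if (!is.null(streams)) {
    say("stage 4/4: energetic efficiency")
    if (!field_dataset %in% zoo$winner$datasets)
      stop("field dataset ", field_dataset, " absent from the trials; ",
           "cannot run the energetics stage")
    eff <- energetic_efficiency(
      streams, zoo$winner, met, dataset = field_dataset,
      prey = config$prey, assim = config$assimilation,
      predator_mass_mg = config$predator_mass_mg,
      field_rate_multiplier = config$field_rate_multiplier,
      area_scaling = config$area_scaling, constants = config$constants)
    write.csv(cbind(config_hash = cfg_hash, eff),
              file.path(out_dir, "efficiency.csv"), row.names = FALSE)
    profiles <- efficiency_profiles(eff)
    smr <- lapply(profiles[intersect(c("temperature", "abundance"),
                                     names(profiles))],
                  function(s) s[setdiff(names(s), "fit")])
    writeLines(jsonlite::toJSON(smr, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "efficiency_smoothers.json"))
  }
  say("done: ", out_dir)
  invisible(list(mortality = mort, zoo = zoo, metabolism = met,
                 efficiency = eff, profiles = profiles,
                 out_dir = out_dir, config_hash = cfg_hash))
}
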