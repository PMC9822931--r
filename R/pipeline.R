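#' Run configuration for the analysis pipeline
#'
#' Loads (or normalises) the configuration driving [cape_run()]. A
#' config is a flat named list; unknown keys are kept, missing ones
#' take the documented defaults. One master `seed` governs every
#' stochastic stage, offset deterministically per stage, so a whole
#' pipeline run is reproducible from its config alone.
#'
#' @param x path to a YAML file, or a named list.
#' @return A list of class `run_config` with at least: `seed` (default
#'   1), `n_bins` (6), `n_boot` (10000), `threshold` (`"auto"` or
#'   J kg^-1), `hours_utc` (17-23), `delta_floor` (1), `percentile_q`
#'   (90), `output_dir` (`"."`).
#' @export
run_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  stopifnot(is.list(cfg))
  defaults <- list(seed = 1L, n_bins = 6L, n_boot = 10000L,
                   threshold = "auto", hours_utc = 17:23,
                   delta_floor = 1, percentile_q = 90, output_dir = ".")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = c("run_config", "list"))
}

# per-stage deterministic seed offsets from the master seed
.stage_seed <- function(cfg, stage) {
  offs <- c(simulate_field = 101L, simulate_events = 211L,
            simulate_esm = 307L, bootstrap = 401L)
  (as.integer(cfg$seed) + offs[[stage]]) %% .Machine$integer.max
}

.out_path <- function(cfg, name) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$output_dir, name)
}

.write_log <- function(cfg, subcommand, artifacts) {
  lines <- c(
    sprintf("windcape %s | %s | windcape %s | R %s",
            subcommand, format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            as.character(utils::packageVersion("windcape")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("config: %s", jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)),
    sprintf("artifact: %s", artifacts))
  log_path <- .out_path(cfg, sprintf("windcape-%s.log", subcommand))
  writeLines(lines, log_path)
  invisible(log_path)
}

#' Run one pipeline stage
#'
#' Chains the package's stages the way the study's workflow does, each
#' reading and writing the plain-text formats of the I/O layer. Every
#' run writes a log (config echo, seed, versions) next to its outputs.
#'
#' Subcommands:
#' \describe{
#'   \item{`simulate`}{generate a synthetic baseline CAPE field,
#'     windthrow events, and an ESM ensemble (writes
#'     `baseline.csv`, `events.csv`, `esm-XX-{current,future}.csv`).}
#'   \item{`cape`}{compute parcel CAPE for a sounding CSV
#'     (`config$sounding`, plus `surface_pressure`,
#'     `surface_temperature`, `surface_humidity`); writes `cape.json`.}
#'   \item{`aggregate`}{afternoon-mean a set of hourly field CSVs
#'     (`config$fields`, `config$times` as ISO datetimes); writes
#'     `afternoon-mean.csv`.}
#'   \item{`fit`}{fit the density model from `config$events` and
#'     `config$field`; writes `density-model.json`.}
#'   \item{`bootstrap`}{add bootstrap SDs to a fitted model
#'     (`config$model`, `config$events`, `config$field`).}
#'   \item{`project`}{project ESM pairs (`config$esm`, a list of
#'     `name`/`current`/`future` path triples) against
#'     `config$baseline` with `config$model`; writes Table-style CSV
#'     and full-precision JSON.}
#'   \item{`densitymap`}{grid events (`config$events`) onto a
#'     `config$resolution`-degree map over `config$bounds`; writes
#'     `density-map.csv`.}
#' }
#'
#' @param subcommand one of the stage names above.
#' @param config a [run_config()] (or list/path coercible to one).
#' @return Invisibly, a character vector of artifact paths written.
#' @export
cape_run <- function(subcommand, config = run_config()) {
  cfg <- run_config(config)
  subcommand <- match.arg(subcommand,
                          c("simulate", "cape", "aggregate", "fit",
                            "bootstrap", "project", "densitymap"))
  arts <- switch(subcommand,
    simulate = {
      sc <- synthetic_scenario(seed = .stage_seed(cfg, "simulate_field"))
      baseline <- make_cape_field(sc)
      events <- simulate_windthrows(baseline, sc$intensity_fn,
                                    .stage_seed(cfg, "simulate_events"))
      ens <- make_esm_ensemble(baseline, sc$esm_params,
                               .stage_seed(cfg, "simulate_esm"))
      paths <- c(write_cape_field(baseline, .out_path(cfg, "baseline.csv")),
                 write_events(events, .out_path(cfg, "events.csv")))
      for (m in ens) {
        paths <- c(paths,
          write_cape_field(m$current_cmip, .out_path(cfg,
            sprintf("%s-current.csv", tolower(m$model_name)))),
          write_cape_field(m$future_cmip, .out_path(cfg,
            sprintf("%s-future.csv", tolower(m$model_name)))))
      }
      paths
    },
    cape = {
      prof <- read_sounding(cfg$sounding, cfg$surface_pressure,
                            cfg$surface_temperature, cfg$surface_humidity)
      val <- compute_cape(prof)
      p <- .out_path(cfg, "cape.json")
      jsonlite::write_json(list(cape_j_per_kg = val), p, auto_unbox = TRUE,
                           digits = NA)
      p
    },
    aggregate = {
      fields <- lapply(cfg$fields, read_cape_field)
      times <- as.POSIXct(cfg$times, tz = "UTC")
      mean_f <- afternoon_mean_cape(fields, times, hours_utc = cfg$hours_utc)
      write_cape_field(mean_f, .out_path(cfg, "afternoon-mean.csv"))
    },
    fit = {
      field <- read_cape_field(cfg$field)
      events <- read_events(cfg$events)
      capes <- sample_cape_at_points(field, events)
      model <- fit_density_model(capes, field, n_bins = cfg$n_bins,
                                 threshold = cfg$threshold)
      write_density_model(model, .out_path(cfg, "density-model.json"))
    },
    bootstrap = {
      model <- read_density_model(cfg$model)
      field <- read_cape_field(cfg$field)
      events <- read_events(cfg$events)
      capes <- sample_cape_at_points(field, events)
      model$bootstrap_sd <- bootstrap_density_sd(
        capes, model, n_boot = cfg$n_boot, seed = .stage_seed(cfg, "bootstrap"))
      write_density_model(model, .out_path(cfg, "density-model.json"))
    },
    project = {
      baseline <- read_cape_field(cfg$baseline, provenance = "baseline")
      model <- read_density_model(cfg$model)
      results <- lapply(cfg$esm, function(e) {
        project_model(e$name,
                      read_cape_field(e$current), read_cape_field(e$future),
                      baseline, model, floor = cfg$delta_floor)
      })
      summ <- ensemble_summary(results)
      c(write_projection_csv(summ, .out_path(cfg, "projection.csv")),
        write_projection_json(summ, .out_path(cfg, "projection.json")))
    },
    densitymap = {
      events <- read_events(cfg$events)
      g <- grid_spec(cfg$resolution %||% 2.5, unlist(cfg$bounds))
      write_density_map(grid_density_map(events, g),
                        .out_path(cfg, "density-map.csv"))
    })
  .write_log(cfg, subcommand, arts)
  invisible(arts)
}
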