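#' Run the end-to-end monitoring pipeline
#'
#' Batch detection over a recording manifest, hourly aggregation through the
#' duty-cycle schedule, and (when surveys are supplied) correlation of
#' site x period buzz rates against standardised survey counts. All outputs
#' are plain CSV under `out_dir`, each preceded by a one-line `#` provenance
#' comment (config hash, seed, package version); read them back with
#' `read.csv(..., comment.char = "#")`. A `provenance.json` with the same
#' fields is written alongside.
#'
#' @param cfg A list (see [pipeline_config()]).
#' @return Invisibly, a list with the detection tables, activity series and
#'   (if computed) the correlation result.
#' @export
run_pipeline <- function(cfg) {
  cfg <- do.call(pipeline_config, cfg[!vapply(cfg, is.null, TRUE)])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- read_manifest(cfg$manifest)
  det_cfg <- if (is.character(cfg$detector)) read_detector_config(cfg$detector)
             else cfg$detector
  sched <- if (is.character(cfg$schedule)) read_schedule(cfg$schedule)
           else cfg$schedule
  prov <- list(
    config_hash = sprintf("%08x", digest32(deparse(cfg[setdiff(names(cfg), "out_dir")]))),
    seed = cfg$seed,
    tool = paste0("buzzcount ", as.character(utils::packageVersion("buzzcount"))))
  write_prov_csv <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    writeLines(sprintf("# %s seed=%s config=%s", prov$tool, prov$seed,
                       prov$config_hash), path)
    suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                        append = TRUE, qmethod = "double"))
    path
  }
  det <- detect_batch(man, det_cfg)
  write_prov_csv(det$events, "events.csv")
  write_prov_csv(det$summary, "summary.csv")

  ev <- detections_to_events(det)
  devices <- unique(man[c("device_id", "site_id")])
  span <- range(man$start_time)
  act <- activity_series(ev, sched,
                         start = as.POSIXct(trunc(span[1], "days")),
                         end = as.POSIXct(trunc(span[2], "days")) + 86400,
                         devices = devices)
  act_out <- act
  act_out$hour_start <- format(act$hour_start, "%Y-%m-%dT%H:%M:%S")
  write_prov_csv(act_out, "activity.csv")

  corr <- NULL
  if (!is.null(cfg$surveys)) {
    surveys <- standardize_counts(utils::read.csv(cfg$surveys, comment.char = "#"))
    periods <- if (is.character(cfg$periods))
      utils::read.csv(cfg$periods, comment.char = "#") else cfg$periods
    if (is.null(periods)) stop("surveys given but no periods table", call. = FALSE)
    spb <- site_period_buzz(act, periods, window_hours = cfg$window_hours)
    corr <- correlate_surveys(spb, surveys, method = cfg$survey_method)
    write_prov_csv(corr$data, "correlation_data.csv")
    report <- data.frame(method = cfg$survey_method, r = corr$r, p = corr$p,
                         n = corr$n)
    write_prov_csv(report, "correlation.csv")
  }
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(list(detections = det, activity = act, correlation = corr,
                 provenance = prov))
}

#' Pipeline run configuration
#'
#' @param manifest Path to a recording-manifest CSV.
#' @param out_dir Output directory.
#' @param detector A [detector_config()] or path to its JSON.
#' @param schedule A [duty_cycle_schedule()] or path to its JSON.
#' @param surveys Optional path to a survey-counts CSV (`site_id, period,
#'   method, n_replicates, total_abundance[, flying_abundance]`).
#' @param periods Optional periods table (`period, start, end`) or CSV path;
#'   required with `surveys`.
#' @param survey_method Survey method for the correlation report.
#' @param window_hours Daily analysis window for survey comparison.
#' @param seed Seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return Validated config list.
#' @export
pipeline_config <- function(manifest, out_dir, detector = detector_config(),
                            schedule = duty_cycle_schedule(), surveys = NULL,
                            periods = NULL, survey_method = "pan_trap",
                            window_hours = 10:15, seed = 1L) {
  for (p in c(manifest, if (is.character(detector)) detector,
              if (is.character(schedule)) schedule, surveys,
              if (is.character(periods)) periods))
    if (!file.exists(p)) stop("config error: missing file ", p, call. = FALSE)
  list(manifest = manifest, out_dir = out_dir, detector = detector,
       schedule = schedule, surveys = surveys, periods = periods,
       survey_method = survey_method, window_hours = window_hours, seed = seed)
}

# small polynomial rolling hash for provenance stamping (not cryptographic)
digest32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  h
}

#' Command-line interface
#'
#' Entry point behind the `buzz` script shipped in `inst/cli/buzz.R`
#' (`Rscript -e 'quit(status = buzzcount::buzz_cli())'` style). Subcommands:
#' \describe{
#'   \item{simulate}{`buzz simulate --out DIR [--days N] [--devices N]
#'     [--seed S] [--base-rate R]` — render a synthetic scenario (WAVs,
#'     manifest, ground truth).}
#'   \item{detect}{`buzz detect WAV [--config C.json] [--out-events E.csv]
#'     [--out-summary S.csv]` — single-file detection.}
#'   \item{batch}{`buzz batch MANIFEST.csv [--config C.json] ...` — batch
#'     detection.}
#'   \item{aggregate}{`buzz aggregate EVENTS.csv --out ACTIVITY.csv
#'     [--schedule S.json]` — hourly activity series.}
#'   \item{correlate}{`buzz correlate ACTIVITY.csv SURVEYS.csv PERIODS.csv
#'     [--method pan_trap]` — site x period Pearson correlation.}
#'   \item{run}{`buzz run CONFIG.json` — full pipeline via [run_pipeline()].}
#' }
#' Exit codes: 0 success, 2 config/usage error, 3 data error.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
buzz_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: buzz <simulate|detect|batch|aggregate|correlate|run> ..."
  if (length(args) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]; rest <- args[-1L]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 1L && i < length(rest)) rest[i + 1L] else default
  }
  pos <- function() rest[!startsWith(rest, "--") &
                           !seq_along(rest) %in% (which(startsWith(rest, "--")) + 1L)]
  status <- tryCatch({
    switch(cmd,
      simulate = {
        out <- opt("--out"); if (is.null(out)) stop("config error: --out required")
        spec <- scenario_spec(days = as.integer(opt("--days", "1")),
                              n_devices = as.integer(opt("--devices", "1")),
                              base_rate = as.numeric(opt("--base-rate", "30")),
                              seed = as.integer(opt("--seed", "1")))
        gt <- sample_event_times(spec)
        render_scenario(gt, spec, duty_cycle_schedule(), out)
        message("wrote scenario to ", out)
        0L
      },
      detect = ,
      batch = {
        p <- pos(); if (length(p) < 1L) stop("config error: input file required")
        cfgp <- opt("--config")
        dcfg <- if (is.null(cfgp)) detector_config() else read_detector_config(cfgp)
        man <- if (cmd == "batch") read_manifest(p[1L]) else
          data.frame(path = p[1L], device_id = "dev0", site_id = "site0",
                     start_time = as.POSIXct("2023-01-01 00:00:00", tz = "UTC"))
        det <- detect_batch(man, dcfg)
        write_detections(det, opt("--out-events"), opt("--out-summary"))
        message(sum(det$summary$count), " events in ", nrow(man), " recording(s)")
        0L
      },
      aggregate = {
        p <- pos(); if (length(p) < 1L) stop("config error: events CSV required")
        out <- opt("--out"); if (is.null(out)) stop("config error: --out required")
        sp <- opt("--schedule")
        sched <- if (is.null(sp)) duty_cycle_schedule() else read_schedule(sp)
        e <- utils::read.csv(p[1L], comment.char = "#")
        ev <- data.frame(device_id = e$device_id, site_id = e$site_id,
                         event_time = parse_iso_time(e$start_time) + e$event_start_s)
        act <- activity_series(ev, sched)
        act$hour_start <- format(act$hour_start, "%Y-%m-%dT%H:%M:%S")
        utils::write.csv(act, out, row.names = FALSE)
        0L
      },
      correlate = {
        p <- pos(); if (length(p) < 3L)
          stop("config error: need ACTIVITY.csv SURVEYS.csv PERIODS.csv")
        act <- utils::read.csv(p[1L], comment.char = "#")
        act$hour_start <- parse_iso_time(act$hour_start)
        surveys <- standardize_counts(utils::read.csv(p[2L], comment.char = "#"))
        periods <- utils::read.csv(p[3L], comment.char = "#")
        spb <- site_period_buzz(act, periods)
        res <- correlate_surveys(spb, surveys, method = opt("--method", "pan_trap"))
        cat(sprintf("r = %.3f, N = %d, P = %.4f\n", res$r, res$n, res$p))
        0L
      },
      run = {
        p <- pos(); if (length(p) < 1L) stop("config error: CONFIG.json required")
        cfg <- jsonlite::read_json(p[1L], simplifyVector = TRUE)
        run_pipeline(cfg)
        0L
      },
      { message(usage); 2L }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("config error|missing file|usage", conditionMessage(e))) 2L else 3L
  })
  invisible(status)
}
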