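#' Run one stage of the frost-reconstruction pipeline
#'
#' File-based orchestration so that each stage is independently runnable
#' and testable. Stages communicate through the standard formats: RWL
#' ring widths under `rwl/`, daily climate CSV under `climate/`, monthly
#' CSV under `monthly/`, the YAML configuration, and the event-table CSV.
#'
#' * `simulate` -- generate a synthetic study system ([simulate_network()])
#'   and write all of its inputs plus `truth.csv` into `outdir`;
#' * `chronology` -- build site chronologies for every RWL file and write
#'   `chronologies.csv` (site, year, index, depth) and
#'   `chronology_stats.csv`;
#' * `climate` -- write the per-region annual climate indices to
#'   `climate_indices.csv`;
#' * `detect` -- run [reconstruct_events()] and write `events.csv` and
#'   `report.txt`;
#' * `report` -- summarize an existing `events.csv` to the console.
#'
#' Every stage records a `manifest_<stage>.yml` with the configuration
#' hash, input files, seed and outputs; identical manifests imply
#' identical outputs.
#'
#' @param stage One of `"simulate"`, `"chronology"`, `"climate"`,
#'   `"detect"`, `"report"`.
#' @param outdir Working directory for stage inputs/outputs.
#' @param config Path to the YAML configuration (defaults to
#'   `outdir/config.yml`).
#' @param seed Integer seed (used by `simulate`).
#' @param params Optional [simulation_params()] overriding the default
#'   generator settings for `simulate`.
#' @return Invisibly, a list of the stage's main artifacts.
#' @export
run_pipeline <- function(stage = c("simulate", "chronology", "climate",
                                   "detect", "report"),
                         outdir = ".", config = NULL, seed = 1L,
                         params = NULL) {
  stage <- match.arg(stage)
  if (is.null(config)) config <- file.path(outdir, "config.yml")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         simulate = stage_simulate(outdir, seed, params),
         chronology = stage_chronology(outdir, config),
         climate = stage_climate(outdir, config),
         detect = stage_detect(outdir, config),
         report = stage_report(outdir))
}

write_manifest <- function(outdir, stage, config_path, inputs, seed,
                           outputs) {
  manifest <- list(
    stage = stage,
    config_md5 = if (!is.null(config_path) && file.exists(config_path))
      unname(tools::md5sum(config_path)) else NA,
    inputs = as.list(sort(basename(inputs))),
    seed = seed,
    package_version = as.character(utils::packageVersion("frostdendro")),
    outputs = as.list(sort(basename(outputs))))
  yaml::write_yaml(manifest,
                   file.path(outdir, sprintf("manifest_%s.yml", stage)))
}

stage_simulate <- function(outdir, seed, params) {
  if (is.null(params)) params <- simulation_params(seed = seed)
  sim <- simulate_network(params)
  rwl_dir <- file.path(outdir, "rwl")
  clim_dir <- file.path(outdir, "climate")
  mon_dir <- file.path(outdir, "monthly")
  for (d in c(rwl_dir, clim_dir, mon_dir))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  for (rw in c(sim$target, sim$control))
    outputs <- c(outputs,
                 write_rwl(rw, file.path(rwl_dir,
                                         paste0(rw$site_code, ".rwl"))))
  for (r in names(sim$stations))
    for (st in sim$stations[[r]])
      outputs <- c(outputs, write_daily_climate(
        st, file.path(clim_dir,
                      paste0(attr(st, "station_id"), ".csv"))))
  for (r in names(sim$monthly)) {
    outputs <- c(outputs,
                 write_monthly_climate(sim$monthly[[r]]$temp,
                   file.path(mon_dir, paste0(r, "_temp.csv"))),
                 write_monthly_climate(sim$monthly[[r]]$prec,
                   file.path(mon_dir, paste0(r, "_prec.csv"))))
  }
  cfg_path <- file.path(outdir, "config.yml")
  write_detection_config(sim$config, cfg_path)
  truth_path <- file.path(outdir, "truth.csv")
  write.csv(sim$truth, truth_path, row.names = FALSE, na = "")
  write_manifest(outdir, "simulate", cfg_path, character(), seed,
                 c(outputs, cfg_path, truth_path))
  invisible(list(sim = sim, config = cfg_path))
}

load_stage_inputs <- function(outdir, config_path, need_control = TRUE) {
  cfg <- read_detection_config(config_path)
  rwl_dir <- file.path(outdir, "rwl")
  clim_dir <- file.path(outdir, "climate")
  mon_dir <- file.path(outdir, "monthly")
  read_sites <- function(codes, species) {
    out <- list()
    for (s in codes) {
      f <- file.path(rwl_dir, paste0(s, ".rwl"))
      if (!file.exists(f)) stop("missing ring-width file: ", f)
      out[[s]] <- read_rwl(f, site_code = s, species = species)
    }
    out
  }
  target <- list(); control <- list(); stations <- list(); monthly <- list()
  for (r in names(cfg$regions)) {
    reg <- cfg$regions[[r]]
    target <- c(target, read_sites(reg$sites, "target"))
    if (need_control)
      control <- c(control,
                   read_sites(reg$control_sites %||% character(),
                              "control"))
    stations[[r]] <- lapply(reg$stations, function(id) {
      f <- file.path(clim_dir, paste0(id, ".csv"))
      if (!file.exists(f)) stop("missing daily climate file: ", f)
      read_daily_climate(f, station_id = id)
    })
    tf <- file.path(mon_dir, paste0(r, "_temp.csv"))
    pf <- file.path(mon_dir, paste0(r, "_prec.csv"))
    if (!file.exists(tf) || !file.exists(pf))
      stop("missing monthly climate file(s) for region ", r)
    monthly[[r]] <- list(temp = read_monthly_climate(tf, "temp"),
                         prec = read_monthly_climate(pf, "prec"))
  }
  list(config = cfg, target = target, control = control,
       stations = stations, monthly = monthly)
}

stage_chronology <- function(outdir, config_path) {
  inp <- load_stage_inputs(outdir, config_path)
  chron <- lapply(c(inp$target, inp$control), build_site_chronology)
  rows <- do.call(rbind, lapply(chron, function(ch) {
    ok <- is.finite(ch$index)
    data.frame(site = ch$site_code, year = ch$years[ok],
               index = ch$index[ok], depth = ch$depth[ok])
  }))
  stats <- do.call(rbind, lapply(chron, function(ch)
    cbind(site = ch$site_code, ch$stats)))
  f1 <- file.path(outdir, "chronologies.csv")
  f2 <- file.path(outdir, "chronology_stats.csv")
  write.csv(rows, f1, row.names = FALSE)
  write.csv(stats, f2, row.names = FALSE)
  write_manifest(outdir, "chronology", config_path,
                 list.files(file.path(outdir, "rwl")), NA, c(f1, f2))
  invisible(list(chronologies = chron, files = c(f1, f2)))
}

stage_climate <- function(outdir, config_path) {
  inp <- load_stage_inputs(outdir, config_path, need_control = FALSE)
  tabs <- lapply(names(inp$config$regions), function(r)
    cbind(region = r, regional_climate(inp$stations[[r]], inp$config)))
  tab <- do.call(rbind, tabs)
  f <- file.path(outdir, "climate_indices.csv")
  write.csv(tab, f, row.names = FALSE)
  write_manifest(outdir, "climate", config_path,
                 list.files(file.path(outdir, "climate")), NA, f)
  invisible(list(climate = tab, file = f))
}

stage_detect <- function(outdir, config_path) {
  inp <- load_stage_inputs(outdir, config_path)
  rec <- reconstruct_events(inp$target, inp$control, inp$stations,
                            inp$monthly, inp$config)
  ev_path <- file.path(outdir, "events.csv")
  write_event_table(rec$events, ev_path)
  rpt_path <- file.path(outdir, "report.txt")
  con <- file(rpt_path, "w")
  writeLines(c(
    sprintf("Frost reconstruction: %d site-years evaluated, %d event rows",
            nrow(rec$criteria), nrow(rec$events)),
    sprintf("  %s: %d", levels(rec$events$confidence),
            as.integer(table(rec$events$confidence))),
    "", "Events:"), con)
  if (nrow(rec$events))
    writeLines(apply(rec$events, 1L, function(x)
      sprintf("  %s %s %s [%s] min %s/%s C %s doy %s", x["region"],
              x["site"], x["year"], x["confidence"], x["win_min_1"],
              x["win_min_2"], x["co_drivers"], x["pinpoint_doy"])), con)
  if (!is.null(rec$report$skipped)) {
    writeLines(c("", "Skipped site-years:"), con)
    writeLines(sprintf("  %s %s: %s", rec$report$skipped$site,
                       rec$report$skipped$year,
                       rec$report$skipped$reason), con)
  }
  close(con)
  write_manifest(outdir, "detect", config_path,
                 c(list.files(file.path(outdir, "rwl")),
                   list.files(file.path(outdir, "climate")),
                   list.files(file.path(outdir, "monthly"))),
                 NA, c(ev_path, rpt_path))
  invisible(list(reconstruction = rec, events = ev_path,
                 report = rpt_path))
}

stage_report <- function(outdir) {
  f <- file.path(outdir, "events.csv")
  if (!file.exists(f)) stop("missing event table: ", f)
  ev <- read_event_table(f)
  print(ev)
  invisible(list(events = ev))
}
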