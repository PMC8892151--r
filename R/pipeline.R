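#' Default pipeline configuration
#'
#' Encodes the default study conditions: two incubation runs, six feeds,
#' four replicates per run per feed and 12 blanks per technique; the
#' automated technique in 140-mL bottles with 60 mL of buffered rumen fluid
#' read and vented every 15 min for 48 h; the manual technique in 60-mL
#' serum bottles with 30 mL fluid read and vented at 2, 4, 6, 8, 12, 16,
#' 24, 36 and 48 h.
#'
#' @param seed Integer seed driving every random draw of the pipeline.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param endpoints Hours summarized in the report.
#' @param convention Volume convention, see [pressure_to_volume()].
#' @param vc_method Variance-component method for the repeatability stage.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1, out_dir = NULL,
                               endpoints = c(6, 12, 24, 48),
                               convention = "net", vc_method = "reml") {
  list(
    seed = seed, out_dir = out_dir, endpoints = endpoints,
    convention = convention, vc_method = vc_method,
    n_runs = 2, feeds = names(default_feed_params()), n_reps = 4,
    n_blanks = 12,
    feed_params = default_feed_params(),
    apparatus = list(
      automated = apparatus_config(bottle_volume = 140, fluid_volume = 60),
      # half the fluid of the automated bottles, hence half the dissolved-
      # gas capacity (solubility scales with liquid volume)
      manual = apparatus_config(bottle_volume = 60, fluid_volume = 30,
                                solubility_coeff = 0.25)),
    schedules = list(
      automated = venting_schedule("interval", interval = 0.25,
                                   horizon = 48),
      manual = venting_schedule("timepoints",
                                timepoints = c(2, 4, 6, 8, 12, 16, 24, 36,
                                               48), horizon = 48)),
    log_table = NULL, design = NULL)
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [default_run_config()] may be overridden; structured
#' fields (apparatus, schedules, feed parameters) accept the same nested
#' keys as the constructors.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (k in intersect(names(raw), c("seed", "out_dir", "endpoints",
                                    "convention", "vc_method", "n_runs",
                                    "feeds", "n_reps", "n_blanks")))
    cfg[[k]] <- raw[[k]]
  if (!is.null(raw$feed_params))
    cfg$feed_params <- lapply(raw$feed_params, function(p)
      fermentation_params(p$B_true, p$c_true, p$L_true,
                          dm_mass = if (is.null(p$dm_mass)) 0.2 else
                            p$dm_mass))
  cfg
}

validate_run_config <- function(config) {
  has_logs <- !is.null(config$log_table) && !is.null(config$design)
  has_sim <- !is.null(config$feeds) && !is.null(config$schedules)
  if (!has_logs && !has_sim)
    stop("config must provide either pressure logs + design or ",
         "simulation parameters")
  invisible(TRUE)
}

#' Run the full gas-production analysis pipeline
#'
#' Simulate (or ingest) pressure logs, cumulate and convert them to
#' volumes, blank-correct, fit the kinetic model per bottle, and summarize
#' technique/feed means and repeatability. Deterministic given
#' `config$seed`. When `config$out_dir` is set, every intermediate table is
#' written there (`pressure_log.csv`, `gp.csv`, `fits.csv`,
#' `repeatability.json`, `summary.txt`).
#'
#' @param config A `run_config`, see [default_run_config()].
#' @return A report bundle: list with `design`, `log_table`, `gp`,
#'   `summary` (from [technique_feed_means()]), `repeatability`, `fits`,
#'   `truth` (when simulated), `timings` (seconds per stage).
#' @export
run_pipeline <- function(config = default_run_config()) {
  validate_run_config(config)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0) timings <<- c(timings,
                                            stats::setNames(tic() - t0, name))

  t0 <- tic()
  truth <- NULL
  if (is.null(config$log_table)) {
    design <- do.call(rbind, lapply(names(config$schedules), function(tech)
      generate_design(config$n_runs, config$feeds, config$n_reps,
                      config$n_blanks, technique = tech)))
    exp <- generate_experiment(design, config$feed_params,
                               apparatus = config$apparatus,
                               schedules = config$schedules,
                               seed = config$seed)
    log_table <- pressure_log_table(exp)
    truth <- exp$truth
  } else {
    design <- config$design
    log_table <- config$log_table
  }
  stage("simulate", t0)

  t0 <- tic()
  v0 <- vapply(config$apparatus, function(a) a$headspace_volume, numeric(1))
  p_atm <- config$apparatus[[1]]$p_atm
  gp <- build_gp_table(log_table, design, headspace_volume = v0,
                       p_atm = p_atm, convention = config$convention)
  gp <- blank_correct_table(gp, design)
  stage("volumetrics", t0)

  t0 <- tic()
  summary_tables <- technique_feed_means(gp, config$endpoints)
  rep_report <- repeatability_report(gp, config$endpoints,
                                     method = config$vc_method)
  stage("repeatability", t0)

  t0 <- tic()
  feed_gp <- gp[gp$feed_id != "blank", ]
  fits <- fit_kinetics_table(feed_gp)
  stage("kinetics", t0)

  bundle <- list(design = design, log_table = log_table, gp = gp,
                 summary = summary_tables, repeatability = rep_report,
                 fits = fits, truth = truth, timings = timings)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$log_table,
                   file.path(out_dir, "pressure_log.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$gp, file.path(out_dir, "gp.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(repeatability = bundle$repeatability,
         technique_means = bundle$summary$technique_means,
         pct_diff = as.list(bundle$summary$pct_diff)),
    file.path(out_dir, "repeatability.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_summary(bundle), file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Plain-text summary of a pipeline report bundle
#'
#' Technique means, feed means, percent technique difference and the
#' repeatability statistics per endpoint, in a layout mirroring the
#' published summary table of the validation experiment.
#'
#' @param bundle Output of [run_pipeline()].
#' @return Character vector of lines.
#' @export
format_summary <- function(bundle) {
  s <- bundle$summary
  eps <- sort(unique(s$technique_means$endpoint_h))
  hdr <- paste0("Item", paste(sprintf("  GP_%g", eps), collapse = ""))
  row_for <- function(label, values)
    paste0(sprintf("%-16s", label),
           paste(sprintf("%8.1f", values), collapse = ""))
  lines <- c("Cumulative gas production (mL/g incubated DM)", hdr,
             "Technique")
  for (tech in unique(s$technique_means$technique)) {
    v <- vapply(eps, function(e)
      s$technique_means$value[s$technique_means$technique == tech &
                                s$technique_means$endpoint_h == e],
      numeric(1))
    lines <- c(lines, row_for(paste0("  ", tech), v))
  }
  lines <- c(lines, row_for("  % difference", unname(s$pct_diff)), "Feed")
  fm <- stats::aggregate(value ~ feed_id + endpoint_h, data = s$feed_means,
                         FUN = mean)
  for (fd in unique(fm$feed_id)) {
    v <- vapply(eps, function(e)
      fm$value[fm$feed_id == fd & fm$endpoint_h == e], numeric(1))
    lines <- c(lines, row_for(paste0("  ", fd), v))
  }
  r <- bundle$repeatability
  for (tech in unique(r$technique)) {
    lines <- c(lines, paste0(tech, " repeatability"))
    rt <- vapply(eps, function(e)
      r$RT[r$technique == tech & r$endpoint_h == e], numeric(1))
    rtp <- vapply(eps, function(e)
      r$RT_pct[r$technique == tech & r$endpoint_h == e], numeric(1))
    lines <- c(lines, row_for("  RT", rt), row_for("  RT%", rtp))
  }
  lines
}
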