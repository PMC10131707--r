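# End-to-end pipeline and command-line entry point.
#
# Stages are chained through files (an instance directory in, rota /
# mileage / summary files out) so each stage can be rerun and inspected
# independently, mirroring how the planning workflow is used in
# practice. The JSON summary deliberately excludes wall-clock times so
# identical configurations produce byte-identical outputs; timings go to
# the log.

OBJECTIVE_ALIASES <- c(staff = "min_staffing", miles = "min_miles",
                       lex = "lexicographic")

log_stage <- function(verbose, ...) if (verbose) message("[telerota] ", ...)

#' Run the full planning pipeline
#'
#' Resolves a demand source (an instance directory, a demand history to
#' forecast from, or the synthetic generator), builds availability if
#' requested, solves the rostering program, and writes `rota.csv`,
#' `mileage.csv` and `summary.json` (plus `shortfall.csv` when
#' infeasible) to the output directory.
#'
#' @param config a list: `instance_dir` or `generator` (arguments for
#'   [generator_config()]); optional `history`/`bank_holidays`/`start`/
#'   `days`/`rounding` to forecast demand from records; optional
#'   `availability_seed` to regenerate availability from contract rules;
#'   `objective` (`"staff"`, `"miles"`, `"lex"` or the long mode names);
#'   `seed`; `time_limit`; `out_dir`; `verbose`.
#' @return exit status, invisibly: 0 optimal, 2 infeasible.
#' @export
run_pipeline <- function(config) {
  verbose <- config$verbose %||% TRUE
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  mode <- config$objective %||% "lex"
  if (mode %in% names(OBJECTIVE_ALIASES)) mode <- OBJECTIVE_ALIASES[[mode]]
  mode <- match.arg(mode, OBJECTIVE_MODES)

  t0 <- proc.time()[["elapsed"]]
  instance <- if (!is.null(config$instance_dir)) {
    log_stage(verbose, "reading instance from ", config$instance_dir)
    read_instance_dir(config$instance_dir)
  } else if (!is.null(config$generator)) {
    log_stage(verbose, "generating synthetic instance (seed ", seed, ")")
    gen <- do.call(generator_config,
                   modifyList(config$generator, list(seed = seed)))
    generate_instance(gen)
  } else stop("config needs instance_dir or generator")

  if (!is.null(config$history)) {
    log_stage(verbose, "forecasting demand from ", config$history)
    history <- read_demand_history_csv(config$history)
    holidays <- if (!is.null(config$bank_holidays))
      read_bank_holidays(config$bank_holidays) else as.Date(character())
    model <- fit_demand_model(history, holidays)
    instance$demand <- predict_demand(
      model, instance$horizon, holidays,
      rounding = config$rounding %||% "nearest",
      locations = instance$locations$id)
  }
  if (!is.null(config$availability_seed)) {
    log_stage(verbose, "building availability calendar (seed ",
              config$availability_seed, ")")
    instance$availability <- build_availability(
      instance$staff, instance$horizon, contract_rules(),
      seed = as.integer(config$availability_seed))
  }

  report <- validate_instance(instance)
  if (nrow(report) > 0) {
    hard <- report[report$check != "infeasible_day", , drop = FALSE]
    if (nrow(hard) > 0) {
      print(hard)
      stop("instance fails validation")
    }
  }

  log_stage(verbose, "solving [", mode, "], ",
            nrow(instance$staff), " staff x ", length(instance$horizon),
            " days")
  res <- solve_rota(instance, mode, time_limit = config$time_limit %||% 60,
                    tie_break_seed = seed)
  stats <- res$model_stats
  log_stage(verbose, "model: ", stats$n_variables, " variables, ",
            stats$n_coverage_constraints + stats$n_assignment_constraints,
            " constraints; status ", res$status,
            sprintf(" (%.3f s)", res$wall_time))

  summary <- list(status = res$status, objective_mode = mode,
                  objective_value = res$objective_value,
                  secondary_value = res$secondary_value,
                  model = stats)
  if (res$status == "optimal") {
    audit <- verify_rota(res$rota, instance)
    summary$assignments <- audit$total_assignments
    summary$total_miles <- audit$total_miles
    summary$off_days <- stats$n_assignment_constraints -
      audit$total_assignments
    write_rota_csv(res$rota, instance, file.path(out_dir, "rota.csv"))
    write_mileage_csv(render_mileage(res$rota, instance$distances),
                      file.path(out_dir, "mileage.csv"))
  } else if (!is.null(res$shortfall)) {
    write.csv(res$shortfall, file.path(out_dir, "shortfall.csv"),
              row.names = FALSE)
    summary$shortfall_total <- sum(res$shortfall$shortfall)
    log_stage(verbose, "infeasible: total unmet demand ",
              summary$shortfall_total, " (see shortfall.csv)")
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage(verbose, "wrote ", out_dir,
            sprintf(" (total %.3f s)", proc.time()[["elapsed"]] - t0))
  invisible(if (res$status == "optimal") 0L else 2L)
}

parse_cli <- function(option_list, args, usage) {
  parser <- optparse::OptionParser(option_list = option_list, usage = usage)
  optparse::parse_args(parser, args = args)
}

opt <- optparse::make_option

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `fixture`, `forecast`,
#' `availability`, `schedule`, `report` and `run`. Invoked by the
#' `telerota.R` script shipped in `inst/cli/`.
#'
#' @param argv character vector of arguments (without the program name).
#' @return integer exit status: 0 success/optimal, 1 usage or data
#'   error, 2 infeasible instance.
#' @export
telerota_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: telerota <command> [options]",
    "commands:",
    "  simulate      generate a synthetic instance directory",
    "  fixture       write the shipped case-study instance directory",
    "  forecast      fit the demand regression and predict a demand file",
    "  availability  generate a contract-rule availability calendar",
    "  schedule      solve the rostering program for an instance",
    "  report        score an existing rota (mileage + summary)",
    "  run           full pipeline: instance -> forecast -> solve -> report",
    sep = "\n")
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
    message(usage); return(invisible(1L))
  }
  cmd <- argv[1]; rest <- argv[-1]
  handler <- switch(cmd,
                    simulate = cli_simulate, fixture = cli_fixture,
                    forecast = cli_forecast, availability = cli_availability,
                    schedule = cli_schedule, report = cli_report,
                    run = cli_run, NULL)
  if (is.null(handler)) {
    message("unknown command: ", cmd, "\n", usage)
    return(invisible(1L))
  }
  status <- tryCatch(handler(rest), error = function(e) {
    message("telerota ", cmd, ": ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

cli_simulate <- function(args) {
  o <- parse_cli(list(
    opt("--seed", type = "integer", default = 1L),
    opt("--out", type = "character", default = "instance"),
    opt("--config", type = "character", default = NULL,
        help = "YAML of generator_config overrides")),
    args, "telerota simulate --seed N --out DIR [--config FILE]")
  over <- if (!is.null(o$config)) yaml::read_yaml(o$config) else list()
  cfg <- do.call(generator_config, modifyList(over, list(seed = o$seed)))
  inst <- generate_instance(cfg)
  write_instance_dir(inst, o$out)
  message("wrote instance to ", o$out)
  0L
}

cli_fixture <- function(args) {
  o <- parse_cli(list(opt("--out", type = "character", default = "fixture")),
                 args, "telerota fixture --out DIR")
  inst <- cwtch_instance()
  write_instance_dir(inst, o$out)
  write_rota_csv(cwtch_rota(), inst, file.path(o$out, "rota_published.csv"))
  message("wrote case-study instance to ", o$out)
  0L
}

cli_forecast <- function(args) {
  o <- parse_cli(list(
    opt("--history", type = "character"),
    opt("--holidays", type = "character", default = NULL),
    opt("--start", type = "character"),
    opt("--days", type = "integer", default = 28L),
    opt("--rounding", type = "character", default = "nearest"),
    opt("--out", type = "character", default = "demand.csv")),
    args, "telerota forecast --history FILE --start DATE [--days N] --out FILE")
  history <- read_demand_history_csv(o$history)
  holidays <- if (!is.null(o$holidays)) read_bank_holidays(o$holidays)
              else as.Date(character())
  model <- fit_demand_model(history, holidays)
  horizon <- planning_horizon(o$start, o$days)
  demand <- predict_demand(model, horizon, holidays, rounding = o$rounding)
  long <- expand.grid(location = rownames(demand), date = colnames(demand),
                      stringsAsFactors = FALSE)
  long$demand <- as.vector(demand)
  write.csv(long, o$out, row.names = FALSE)
  message("wrote forecast demand to ", o$out)
  0L
}

cli_availability <- function(args) {
  o <- parse_cli(list(
    opt("--staff", type = "character"),
    opt("--start", type = "character"),
    opt("--days", type = "integer", default = 28L),
    opt("--seed", type = "integer", default = 1L),
    opt("--out", type = "character", default = "availability.csv")),
    args, "telerota availability --staff FILE --start DATE --days N --seed N")
  staff <- read_staff_csv(o$staff)
  horizon <- planning_horizon(o$start, o$days)
  cal <- build_availability(staff, horizon, contract_rules(), seed = o$seed)
  long <- expand.grid(staff = rownames(cal), date = colnames(cal),
                      stringsAsFactors = FALSE)
  long$status <- as.vector(cal)
  write.csv(long, o$out, row.names = FALSE)
  message("wrote availability to ", o$out)
  0L
}

cli_schedule <- function(args) {
  o <- parse_cli(list(
    opt("--instance", type = "character"),
    opt("--objective", type = "character", default = "lex"),
    opt("--seed", type = "integer", default = 1L),
    opt("--time-limit", dest = "time_limit", type = "double", default = 60),
    opt("--out", type = "character", default = "solution")),
    args, "telerota schedule --instance DIR --objective {staff|miles|lex}")
  run_pipeline(list(instance_dir = o$instance, objective = o$objective,
                    seed = o$seed, time_limit = o$time_limit,
                    out_dir = o$out))
}

cli_report <- function(args) {
  o <- parse_cli(list(
    opt("--instance", type = "character"),
    opt("--rota", type = "character"),
    opt("--out", type = "character", default = "report")),
    args, "telerota report --instance DIR --rota FILE --out DIR")
  instance <- read_instance_dir(o$instance)
  r <- read_rota_csv(o$rota, instance)
  audit <- verify_rota(r, instance)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  write_mileage_csv(render_mileage(r, instance$distances),
                    file.path(o$out, "mileage.csv"))
  summary <- list(feasible = audit$feasible,
                  assignments = audit$total_assignments,
                  total_miles = audit$total_miles,
                  violations = nrow(audit$violations))
  jsonlite::write_json(summary, file.path(o$out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("rota: ", if (audit$feasible) "feasible" else "INFEASIBLE",
          ", ", audit$total_assignments, " assignments, ",
          audit$total_miles, " miles")
  if (audit$feasible) 0L else 2L
}

cli_run <- function(args) {
  o <- parse_cli(list(
    opt("--instance", type = "character", default = NULL),
    opt("--config", type = "character", default = NULL,
        help = "YAML pipeline config (overridden by flags)"),
    opt("--history", type = "character", default = NULL),
    opt("--holidays", type = "character", default = NULL),
    opt("--objective", type = "character", default = "lex"),
    opt("--seed", type = "integer", default = 1L),
    opt("--time-limit", dest = "time_limit", type = "double", default = 60),
    opt("--out", type = "character", default = "out")),
    args, "telerota run --instance DIR [--history FILE] --objective MODE")
  config <- if (!is.null(o$config)) yaml::read_yaml(o$config) else list()
  config <- modifyList(config, list(
    instance_dir = o$instance %||% config$instance_dir,
    history = o$history %||% config$history,
    bank_holidays = o$holidays %||% config$bank_holidays,
    objective = o$objective, seed = o$seed,
    time_limit = o$time_limit, out_dir = o$out))
  run_pipeline(config)
}
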