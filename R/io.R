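#' Run configuration
#'
#' A run configuration bundles a scenario choice, protocol fields, solver
#' tolerances and output options. Unspecified fields fall back to the
#' registered defaults, so the fully-defaulted configuration reproduces the
#' standard normal five-session run.
#'
#' @param scenario Scenario name.
#' @param n_sessions,train_hours,rest_hours,d_train,ramp Protocol fields
#'   (see [okr_protocol()]); \code{ramp} is a numeric vector of per-session
#'   factors or \code{NULL} for the default schedule.
#' @param rtol,atol Solver tolerances.
#' @param seed Integer seed, used only for optional observation noise in
#'   fixture generation.
#' @param noise_sd Standard deviation of Gaussian observation noise applied
#'   to fixture gain samples (0 = none).
#' @return Object of class \code{"okr_config"}.
#' @export
okr_config <- function(scenario = "normal", n_sessions = 5,
                       train_hours = 1, rest_hours = 23,
                       d_train = 1.87, ramp = NULL,
                       rtol = 1e-6, atol = 1e-8,
                       seed = 1L, noise_sd = 0) {
  get_scenario(scenario)  # validates the name
  stopifnot(noise_sd >= 0)
  structure(list(scenario = scenario, n_sessions = n_sessions,
                 train_hours = train_hours, rest_hours = rest_hours,
                 d_train = d_train, ramp = ramp, rtol = rtol, atol = atol,
                 seed = as.integer(seed), noise_sd = noise_sd),
            class = "okr_config")
}

#' Load a run configuration from a YAML file
#'
#' The file may set any field of [okr_config()]; unknown keys are rejected
#' with the offending key path. An empty file yields all defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return An \code{"okr_config"} object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("scenario: mf_gc_attenuation", f)
#' load_config(f)$scenario
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop("cannot parse configuration '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("configuration must be a YAML mapping", call. = FALSE)
  known <- names(formals(okr_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         "; known keys: ", paste(known, collapse = ", "), call. = FALSE)
  do.call(okr_config, raw)
}

config_protocol <- function(config) {
  sc <- get_scenario(config$scenario)
  ev <- lapply(sc$events, resolve_event_time,
               protocol = okr_protocol(n_sessions = config$n_sessions,
                                       train_hours = config$train_hours,
                                       rest_hours = config$rest_hours,
                                       d_train = config$d_train))
  okr_protocol(n_sessions = config$n_sessions,
               train_hours = config$train_hours,
               rest_hours = config$rest_hours,
               d_train = config$d_train,
               ramp = config$ramp %||% function(s) pmin(1, s / 3),
               events = ev)
}

#' Run a configuration
#'
#' @param config An \code{"okr_config"} object (or path to a YAML file).
#' @return An \code{"okr_sim"} object.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "okr_config"))
  params <- scenario_params(get_scenario(config$scenario))
  sim <- run_protocol(params, config_protocol(config),
                      rtol = config$rtol, atol = config$atol)
  sim$scenario <- config$scenario
  sim
}

#' Write a simulation trajectory to CSV
#'
#' Columns: \code{t_hours} (6 decimal places), the three weights,
#' \code{gain}, \code{phase}, \code{session}. Comma-separated, UTF-8,
#' '.'-decimal; deterministic byte-identical output for identical runs.
#'
#' @param sim An \code{"okr_sim"} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  tr <- sim$trajectory
  tr$t_hours <- sprintf("%.6f", tr$t_hours)
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write per-session metrics to CSV
#'
#' @param sim An \code{"okr_sim"} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_csv <- function(sim, path) {
  utils::write.csv(session_metrics(sim), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate pinned reference gain curves
#'
#' Writes reference trajectories for the normal, complete climbing-fiber
#' blockade and corticonuclear-block runs, for use as regression baselines
#' and as synthetic stand-ins for behavioural recordings. Gain samples can
#' optionally carry seeded Gaussian observation noise; with
#' \code{noise_sd = 0} the fixtures equal the raw simulator output. Output
#' is deterministic for a fixed seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param config An \code{"okr_config"}; its seed and \code{noise_sd} govern
#'   the observation noise.
#' @param scenarios Scenario names to pin.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(out_dir, config = okr_config(),
                          scenarios = c("normal", "cf_block_complete",
                                        "pc_dn_block")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  paths <- character(0)
  for (nm in scenarios) {
    cfg <- config
    cfg$scenario <- nm
    sim <- run_config(cfg)
    tr <- sim$trajectory
    if (config$noise_sd > 0)
      tr$gain <- tr$gain + stats::rnorm(nrow(tr), 0, config$noise_sd)
    tr$t_hours <- sprintf("%.6f", tr$t_hours)
    tr$gain <- sprintf("%.6f", tr$gain)
    for (cl in c("w_pf_pc", "w_pf_mli", "w_mf_dn"))
      tr[[cl]] <- sprintf("%.6f", tr[[cl]])
    p <- file.path(out_dir, paste0("reference_", nm, ".csv"))
    utils::write.csv(tr, p, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}

cli_log <- function(quiet, ...) {
  if (!quiet) message(...)
}

cli_usage <- function() {
  paste(
    "usage: okrsim <command> [options]",
    "",
    "commands:",
    "  simulate        run one scenario; writes trajectory and metrics CSVs",
    "  compare         tabulate all (or selected) scenarios",
    "  list-scenarios  print the registered scenario names",
    "  make-fixtures   write pinned reference gain curves",
    "",
    "common options:",
    "  --config PATH       YAML run configuration",
    "  --scenario NAME     scenario (default: normal)",
    "  --sessions N        number of sessions",
    "  --d-train X         training desired gain",
    "  --out PATH          output file / directory",
    "  --metrics-out PATH  per-session metrics CSV (simulate)",
    "  --all               all scenarios (compare)",
    "  --quiet             suppress progress messages",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list(quiet = FALSE, all = FALSE)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    take <- function() {
      if (i + 1L > length(argv))
        stop("missing value for option ", a, call. = FALSE)
      i <<- i + 1L
      argv[[i]]
    }
    switch(a,
      "--config" = { opts$config <- take() },
      "--scenario" = { opts$scenario <- take() },
      "--sessions" = { opts$sessions <- as.integer(take()) },
      "--d-train" = { opts$d_train <- as.numeric(take()) },
      "--out" = { opts$out <- take() },
      "--metrics-out" = { opts$metrics_out <- take() },
      "--all" = { opts$all <- TRUE },
      "--quiet" = { opts$quiet <- TRUE },
      stop("unknown option ", a, call. = FALSE))
    i <- i + 1L
  }
  opts
}

cli_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) load_config(opts$config) else okr_config()
  if (!is.null(opts$scenario)) { get_scenario(opts$scenario); cfg$scenario <- opts$scenario }
  if (!is.null(opts$sessions)) cfg$n_sessions <- opts$sessions
  if (!is.null(opts$d_train)) cfg$d_train <- opts$d_train
  cfg
}

#' Command-line interface
#'
#' Entry point behind the installed \code{okrsim} script
#' (\code{system.file("cli", "okrsim.R", package = "okrsim")}). Supports the
#' subcommands \code{simulate}, \code{compare}, \code{list-scenarios} and
#' \code{make-fixtures}; outputs are byte-identical for identical
#' configurations, and the CLI produces exactly the trajectories of the
#' corresponding library calls.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code (0 on success), invisibly.
#' @examples
#' run_cli("list-scenarios")
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    cat(cli_usage(), "\n")
    return(invisible(1L))
  }
  cmd <- argv[[1L]]
  res <- tryCatch({
    opts <- parse_cli_args(argv[-1L])
    switch(cmd,
      "list-scenarios" = {
        cat(list_scenarios(), sep = "\n")
      },
      "simulate" = {
        cfg <- cli_config(opts)
        cli_log(opts$quiet, "simulating scenario '", cfg$scenario, "' (",
                cfg$n_sessions, " sessions)")
        sim <- run_config(cfg)
        out <- opts$out %||% paste0("okrsim_", cfg$scenario, ".csv")
        write_trajectory_csv(sim, out)
        write_metrics_csv(sim, opts$metrics_out %||%
                            sub("\\.csv$", "_metrics.csv", out))
        n <- cfg$n_sessions
        cli_log(opts$quiet, sprintf(
          "final gain %.4f (session %d post-training); wrote %s",
          sim$sessions$gain_post[n], n, out))
      },
      "compare" = {
        cfg <- cli_config(opts)
        nms <- if (opts$all || is.null(opts$scenario)) list_scenarios()
               else opts$scenario
        cli_log(opts$quiet, "comparing ", length(nms), " scenario(s)")
        pr <- config_protocol(cfg)
        tab <- compare_scenarios(nms, pr)
        num <- vapply(tab, is.numeric, logical(1))
        tab[num] <- lapply(tab[num], function(x) sprintf("%.6f", x))
        out <- opts$out %||% "okrsim_comparison.csv"
        utils::write.csv(tab, out, row.names = FALSE, quote = FALSE,
                         fileEncoding = "UTF-8")
        cli_log(opts$quiet, "wrote ", out)
      },
      "make-fixtures" = {
        cfg <- cli_config(opts)
        out <- opts$out %||% "fixtures"
        paths <- make_fixtures(out, cfg)
        cli_log(opts$quiet, "wrote ", length(paths), " fixture file(s) to ", out)
      },
      stop("unknown command '", cmd, "'\n", cli_usage(), call. = FALSE))
    0L
  }, error = function(e) {
    message("okrsim error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}
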