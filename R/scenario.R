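## End-to-end scenario runner: calibrate -> umbrella series -> WHAM +
## bootstrap -> profile statistics, and (for frozen scenarios) calibrate
## -> grid -> interpolation -> minima -> NEB -> decay -> separation trend.
## Every run is reproducible from a master seed and emits a resolved copy
## of its configuration.

.known_config_keys <- c(
  "scenario", "frozen_scenario", "table_file", "out_dir", "seed",
  "temperature", "dt", "friction", "mass",
  "n_windows", "replicas", "window_steps", "burn_in", "store_stride", "k",
  "min_overlap",
  "bins", "lambda_range", "wham_tol", "n_boot", "block_fs",
  "grid_n", "neb_images", "neb_spring",
  "decay_replicas", "decay_steps", "separations",
  "write_trajectories")

#' Build (and validate) a scenario configuration
#'
#' @param scenario thermal scenario id (see [stationary_table()])
#' @param frozen_scenario frozen counterpart id or NA to skip the frozen
#'   pipeline
#' @param out_dir output directory (created if missing)
#' @param seed master seed; all stage seeds derive from it
#' @param ... overrides for the remaining keys (simulation settings,
#'   umbrella schedule, WHAM/bootstrap, grid/NEB, decay, separations).
#'   Unknown keys produce a warning and are carried along.
#' @return a `dpt_config` list
#' @export
scenario_config <- function(scenario = "duplex_thermal",
                            frozen_scenario = NA, out_dir = tempfile("gcdpt_"),
                            seed = 1L, ...) {
  cfg <- list(
    scenario = scenario, frozen_scenario = frozen_scenario,
    table_file = NULL, out_dir = out_dir, seed = as.integer(seed),
    temperature = 310, dt = 0.5, friction = 5, mass = 1,
    n_windows = 64, replicas = 7, window_steps = 16000,
    burn_in = 4000, store_stride = 4, k = 20000, min_overlap = 0.05,
    bins = 120, lambda_range = c(-0.1, 1.1), wham_tol = 1e-6,
    n_boot = 100, block_fs = 50,
    grid_n = 33, neb_images = 32, neb_spring = 1,
    decay_replicas = 20, decay_steps = 4000,
    separations = c(0, 0.23, 0.60),
    write_trajectories = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), .known_config_keys)
  if (length(unknown))
    warning("unknown config keys (carried along): ",
            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "dpt_config")
}

#' Run a full analysis scenario
#'
#' Executes the thermal chain (calibration, umbrella series, WHAM with
#' block bootstrap, reaction-profile statistics) and, when a frozen
#' scenario is configured, the instantaneous-surface chain (grid,
#' interpolation, minima, NEB, tautomer decay, separation trend). Writes
#' the PMF profile, grid CSV, JSON report and a log into `out_dir` and
#' returns the report invisibly. Identical configs and seeds give
#' identical reports.
#'
#' @param config a [scenario_config()]
#' @return the report list, invisibly
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "dpt_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    logf(name, "start")
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (partial outputs in %s)",
                   name, conditionMessage(e), config$out_dir), call. = FALSE))
    logf(name, "done")
    out
  }
  seed_of <- function(i) (config$seed %% 100000L) * 100L + i
  report <- list(scenario = config$scenario, seed = config$seed,
                 package_version = as.character(utils::packageVersion("gcdpt")))

  tab <- stage("load-table", {
    tb <- stationary_table(config$scenario, file = config$table_file)
    if (!nrow(tb)) stop("configuration error: no rows for scenario ",
                        config$scenario)
    tb
  })
  params <- stage("calibrate", calibrate_surface(tab, seed = seed_of(1)))
  write_surface(params, file.path(config$out_dir, "surface.yaml"))
  report$calibration <- list(
    residuals = as.list(params$calibration$residuals),
    stationary = params$calibration$stationary)

  settings <- simulation_settings(
    temperature = config$temperature, dt = config$dt,
    friction = config$friction, mass = config$mass,
    n_steps = config$window_steps, burn_in = config$burn_in,
    store_stride = config$store_stride, seed = seed_of(2))
  trajs <- stage("umbrella", run_umbrella_series(
    params, settings, n_windows = config$n_windows,
    lambda_range = config$lambda_range, k = config$k,
    replicas = config$replicas, min_overlap = config$min_overlap))
  if (isTRUE(config$write_trajectories))
    for (i in seq_along(trajs))
      write_trajectory(trajs[[i]],
                       file.path(config$out_dir,
                                 sprintf("traj_%03d.csv", i)))

  wres <- stage("wham", bootstrap_pmfs(
    trajs, n_boot = config$n_boot, seed = seed_of(3),
    block_fs = config$block_fs, bins = config$bins,
    lambda_range = config$lambda_range, tol = config$wham_tol,
    T = config$temperature))
  write_pmf(wres$pmf, file.path(config$out_dir, "pmf.txt"))
  prof <- stage("profile", analyze_profile(wres$pmf, T = config$temperature,
                                           scenario = config$scenario))
  boot_profiles <- stage("bootstrap-profiles", lapply(wres$replicates,
    function(r) tryCatch(analyze_profile(r, T = config$temperature),
                         error = function(e) NULL)))
  boot_profiles <- Filter(Negate(is.null), boot_profiles)
  rev_frac <- if (length(boot_profiles) >= 2)
    suppressWarnings(reverse_barrier_fraction(
      boot_profiles, "GC->G_minus_C_plus")) else NA_real_
  report$us <- list(
    transitions = prof$transitions,
    stationary = prof$stationary,
    reverse_barrier_pct_step1 = rev_frac,
    wham_iterations = attr(wres$pmf, "iterations"),
    n_boot = wres$n_boot)

  if (!is.na(config$frozen_scenario)) {
    fro <- stage("calibrate-frozen", calibrate_surface(
      stationary_table(config$frozen_scenario, file = config$table_file),
      seed = seed_of(4)))
    grid <- stage("grid", sample_grid(fro, config$grid_n))
    write_grid(grid, file.path(config$out_dir, "grid.csv"))
    interp <- stage("interpolate", interpolate_grid(grid))
    mins <- stage("minima", find_minima(interp))
    mep <- stage("neb", {
      gc <- unlist(mins[mins$state == "GC", c("r1", "r2")])
      gs <- unlist(mins[mins$state == "GstarCstar", c("r1", "r2")])
      neb_path(fro, gc, gs, n_images = config$neb_images,
               spring_k = config$neb_spring)
    })
    fprof <- stage("frozen-profile", analyze_profile(
      mep, T = config$temperature, scenario = config$frozen_scenario))
    report$frozen <- list(minima = mins, via = mep$via,
                          transitions = fprof$transitions,
                          stationary = fprof$stationary)

    decay <- stage("decay", {
      start <- unlist(mins[mins$state == "GstarCstar", c("r1", "r2")])
      dset <- simulation_settings(
        temperature = config$temperature, dt = config$dt,
        friction = config$friction, mass = config$mass,
        n_steps = config$decay_steps, burn_in = 0, store_stride = 1,
        seed = seed_of(5))
      decay_run(params, start, dset, n_replicas = config$decay_replicas)
    })
    classes <- stage("decay-classify", do.call(rbind, lapply(
      decay$trajectories, classify_decay)))
    report$decay <- cbind(decay$first_passage["replica"], classes)

    if (length(config$separations) >= 1) {
      seps <- stage("separation", {
        meps <- lapply(config$separations, function(sv) {
          mn <- find_minima(fro, s = sv)
          gc <- unlist(mn[mn$state == "GC", c("r1", "r2")])
          gs <- unlist(mn[mn$state == "GstarCstar", c("r1", "r2")])
          neb_path(fro, gc, gs, n_images = config$neb_images,
                   spring_k = config$neb_spring, s = sv)
        })
        suppressMessages(separation_trend(meps, config$separations))
      })
      report$separation <- list(energies = seps$energies, fits = seps$fits,
                                asymmetry_correlation =
                                  seps$asymmetry_correlation)
    }
  }

  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  write_report(report, file.path(config$out_dir, "report.json"))
  logf("run", "complete")
  invisible(report)
}
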