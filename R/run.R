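#' Run a simulation subcommand and write its artifacts
#'
#' Dispatches to the batch, competition, plaque, sweep, oracle or
#' fixture generators from a validated configuration, writes the CSV/JSON
#' artifacts into `out_dir`, and logs parameter provenance (default vs
#' override) and the package version into the summary JSON.
#'
#' @param command one of `"batch"`, `"compete"`, `"plaque"`, `"sweep"`,
#'   `"oracle"`, `"fixtures"`.
#' @param cfg a `lin_config` from [build_config()] / [load_config()];
#'   defaults to the command's default configuration.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix for the artifacts.
#' @return list with `summary` (also written as JSON) and `paths` of the
#'   written files, invisibly. For sweeps the exit-relevant field
#'   `summary$n_failed_cells` counts per-cell failures.
#' @export
run_command <- function(command, cfg = default_config(command),
                        out_dir = ".", prefix = command) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(name) file.path(out_dir, paste0(prefix, "_", name))
  paths <- character(0)
  summary <- list(
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("linsim")),
    command = command,
    overridden_keys = as.list(attr(cfg, "overridden")),
    config = cfg[seq_along(cfg)]
  )

  if (command == "batch") {
    pm <- .cfg_wm_params(cfg)
    init <- batch_init(pm, cfg$B0, cfg$n0, cfg$R0, cfg$P0)
    ts <- simulate_batch(pm, init, t_end = cfg$t_end,
                         sample_dt = cfg$sample_dt)
    paths <- write_timeseries_csv(ts, pth("timeseries.csv"))
    summary$final <- as.list(ts[nrow(ts), c("B", "n", "R", "P", "B_tot")])
    summary$crossing_time_min <- phage_crossing_time(ts)
  } else if (command == "compete") {
    out <- competition_outcome(cfg$f_tau, cfg$f_beta, .cfg_response(cfg),
                               cfg$eta, cfg$B0, cfg$n0, cfg$R0, cfg$P0,
                               cfg$t_end, cfg$trigger_mode,
                               sample_dt = cfg$sample_dt)
    paths <- write_timeseries_csv(out$timeseries, pth("timeseries.csv"))
    summary$ratio <- out$ratio
    summary$peak_decline_R <- out$peak_decline_R
    summary$crossing_time_min <- out$crossing_time_min
  } else if (command == "plaque") {
    strain <- switch(cfg$model, MP0 = "r_mutant", MP1 = "lin_phage",
                     stop("plaque model must be 'MP0' or 'MP1'"))
    sim <- simulate_plaque(.cfg_plaque_params(cfg), strain,
                           sample_times = seq(0, cfg$t_end,
                                              by = cfg$sample_dt))
    paths <- c(write_fields_csv(sim$fields, pth("fields.csv")),
               write_metrics_csv(sim$metrics, pth("metrics.csv")))
    summary$final_metrics <- as.list(sim$metrics[nrow(sim$metrics), ])
  } else if (command == "sweep") {
    sw <- sweep_lin_grid(cfg$sweep_mode, cfg$f_tau_grid, cfg$f_beta_grid,
                         .cfg_response(cfg), cfg$eta, cfg$B0, cfg$n0,
                         phage0 = cfg$P0, t_end = cfg$t_end,
                         trigger_mode = cfg$trigger_mode)
    wr <- write_sweep_csv(sw, pth("matrix.csv"), pth("meta.json"))
    paths <- c(wr$csv, wr$json)
    summary$n_failed_cells <- sum(!is.na(sw$errors))
  } else if (command == "oracle") {
    pm <- .cfg_wm_params(cfg, if (cfg$model %in% c("M0", "M1", "MC1"))
      cfg$model else "M0")
    init <- count_state(B = round(cfg$B0 * cfg$V), n = round(cfg$n0 * cfg$V),
                        R = if (pm$model_id != "M1") round(cfg$R0 * cfg$V) else 0,
                        P = if (pm$model_id != "M0") round(cfg$P0 * cfg$V) else 0,
                        V = cfg$V, N_stages = cfg$N)
    ev <- simulate_events(pm, init, seed = cfg$seed, t_end = cfg$t_end,
                          max_events = cfg$max_events)
    paths <- write_timeseries_csv(ev$timeseries, pth("timeseries.csv"))
    summary$counts <- ev$counts
    summary$capped <- ev$capped
  } else if (command == "fixtures") {
    f <- make_fixture(cfg$kind, grid = radial_grid(cfg$R_max, cfg$dr),
                      crossing = cfg$crossing, seed = cfg$seed)
    paths <- if (inherits(f, "radial_field"))
      write_fields_csv(list(f), pth("field.csv"))
    else {
      p <- pth("state.csv")
      utils::write.csv(data.frame(compartment = c("B", "n", "R", "P"),
                                  value = c(f$B, f$n, f$R, f$P)),
                       p, row.names = FALSE, quote = FALSE)
      p
    }
  } else stop("unknown command: ", command)

  json_path <- pth("summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(summary = summary, paths = c(paths, json_path)))
}
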